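# Readers and writers for the small plain-text interchange formats used
# by the pipeline: PLINK-style PED/MAP, trace CSVs, variant TSVs, and
# 16-bit grayscale TIFF images with a JSON pixel-size sidecar.

#' Write pedigree + single-marker genotypes as a PLINK-style PED file
#'
#' Columns: family id, individual id, father, mother, sex (1/2/0),
#' phenotype (2 affected, 1 unaffected, 0 unknown), then one allele pair
#' per marker.
#'
#' @param ped a [pedigree()].
#' @param genotypes data.frame `id`, `a1`, `a2` (or a list of such for
#'   multiple markers); NA written as 0.
#' @param path output file.
#' @param family_id family identifier (default "FAM1").
#' @export
write_ped <- function(ped, genotypes, path, family_id = "FAM1") {
  if (is.data.frame(genotypes)) genotypes <- list(genotypes)
  sex <- ifelse(is.na(ped$sex), 0L, ifelse(ped$sex == "M", 1L, 2L))
  phe <- c(affected = 2L, unaffected = 1L, unknown = 0L)[ped$affection]
  cols <- list(family_id, ped$id,
               ifelse(is.na(ped$father), "0", ped$father),
               ifelse(is.na(ped$mother), "0", ped$mother),
               sex, phe)
  for (g in genotypes) {
    gi <- g[match(ped$id, g$id), ]
    cols <- c(cols, list(ifelse(is.na(gi$a1), 0, gi$a1),
                         ifelse(is.na(gi$a2), 0, gi$a2)))
  }
  utils::write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)),
                     path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
}

#' Read a PLINK-style PED file
#'
#' @param path PED file.
#' @return list with `pedigree` and `genotypes` (list of data.frames
#'   `id`, `a1`, `a2`, one per marker; 0 read as NA).
#' @export
read_ped <- function(path) {
  d <- utils::read.table(path, stringsAsFactors = FALSE)
  if (ncol(d) < 6 || (ncol(d) - 6) %% 2 != 0)
    abort("malformed PED file: %s", path)
  ped <- pedigree(id = d[[2]],
                  father = ifelse(d[[3]] == "0", NA, d[[3]]),
                  mother = ifelse(d[[4]] == "0", NA, d[[4]]),
                  sex = ifelse(d[[5]] == 0, NA, d[[5]]),
                  affection = d[[6]])
  n_markers <- (ncol(d) - 6) / 2
  genotypes <- lapply(seq_len(n_markers), function(k) {
    a1 <- d[[6 + 2 * k - 1]]; a2 <- d[[6 + 2 * k]]
    data.frame(id = as.character(d[[2]]),
               a1 = ifelse(a1 == 0, NA, a1),
               a2 = ifelse(a2 == 0, NA, a2),
               stringsAsFactors = FALSE)
  })
  list(pedigree = ped, genotypes = genotypes)
}

#' Write / read a PLINK-style MAP file (chrom, marker, cM, bp)
#'
#' @param map data.frame `marker`, `chrom`, `cM` (optional `bp`).
#' @param path file path.
#' @export
write_map <- function(map, path) {
  bp <- if ("bp" %in% names(map)) map$bp else round(map$cM * 1e6)
  utils::write.table(data.frame(map$chrom, map$marker, map$cM, bp),
                     path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  d <- utils::read.table(path, stringsAsFactors = FALSE)
  data.frame(marker = d[[2]], chrom = as.character(d[[1]]),
             cM = d[[3]], bp = d[[4]], stringsAsFactors = FALSE)
}

#' Write / read a two-column trace CSV (time_s, value)
#'
#' @param time_s,value trace samples.
#' @param path file path.
#' @export
write_trace_csv <- function(time_s, value, path) {
  utils::write.csv(data.frame(time_s = time_s, value = value),
                   path, row.names = FALSE)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    abort("trace CSV needs columns time_s, value")
  d
}

#' Write / read a candidate-variant TSV
#'
#' @param variants variant data.frame (as from
#'   [generate_variant_table()]).
#' @param path file path.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a sarcomere image as 16-bit grayscale TIFF plus JSON sidecar
#'
#' The sidecar (same path with extension `.json`) records the pixel size
#' in micrometres. Requires the `tiff` package.
#'
#' @param image a `sarcomere_image` or numeric matrix.
#' @param path output TIFF path.
#' @param pixel_size_um needed for bare matrices.
#' @export
write_image_tiff <- function(image, path, pixel_size_um = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("the 'tiff' package is required for TIFF output")
  if (inherits(image, "sarcomere_image")) {
    pixel_size_um <- image$pixel_size_um
    m <- image$intensity
  } else m <- image
  if (is.null(pixel_size_um)) abort("pixel_size_um required")
  m16 <- m / max(m, 1e-12)
  tiff::writeTIFF(m16, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_um = pixel_size_um,
                            max_intensity = max(m)),
                       sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("the 'tiff' package is required for TIFF input")
  m <- tiff::readTIFF(path)
  sidecar <- sub("\\.tiff?$", ".json", path)
  px <- NULL; scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    px <- meta$pixel_size_um
    scale <- meta$max_intensity %||% 1
  }
  structure(list(intensity = m * scale, pixel_size_um = px,
                 truth = NULL, spec = NULL),
            class = "sarcomere_image")
}
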