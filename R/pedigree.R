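# Pedigree container and validation.

#' Construct a pedigree
#'
#' @param id character or integer individual identifiers (unique).
#' @param father,mother identifiers of the parents, NA for founders. Every
#'   individual must have either both parents recorded or neither.
#' @param sex "M"/"F" (or 1/2, PLINK convention); NA allowed.
#' @param affection one of "affected", "unaffected", "unknown" per
#'   individual (PLINK numeric 2/1/0 also accepted).
#' @return a data.frame of class `pedigree` with normalized columns.
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = NA,
                     affection = "unknown") {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) abort("duplicate individual ids")
  father <- as.character(rep_len(father, n))
  mother <- as.character(rep_len(mother, n))
  father[father %in% c("0", "", "NA")] <- NA
  mother[mother %in% c("0", "", "NA")] <- NA
  one_parent <- xor(is.na(father), is.na(mother))
  if (any(one_parent))
    abort("individual %s has exactly one recorded parent (need both or none)",
          id[which(one_parent)[1]])
  missing_ref <- setdiff(c(father, mother), c(id, NA))
  if (length(missing_ref))
    abort("parent id %s not present in pedigree", missing_ref[1])
  sex <- rep_len(sex, n)
  sex <- ifelse(sex %in% c(1, "1", "M", "m"), "M",
                ifelse(sex %in% c(2, "2", "F", "f"), "F", NA))
  affection <- rep_len(affection, n)
  affection <- ifelse(affection %in% c(2, "2", "affected"), "affected",
                      ifelse(affection %in% c(1, "1", "unaffected"),
                             "unaffected", "unknown"))
  ped <- data.frame(id = id, father = father, mother = mother,
                    sex = sex, affection = affection,
                    stringsAsFactors = FALSE)
  # acyclicity as a parent-child digraph (marriage loops are fine)
  topo_order(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# topological order with parents before children; errors on ancestry cycles
topo_order <- function(ped) {
  n <- nrow(ped)
  placed <- rep(FALSE, n)
  names(placed) <- ped$id
  order <- character(0)
  repeat {
    ready <- !placed &
      (is.na(ped$father) | placed[ped$father]) &
      (is.na(ped$mother) | placed[ped$mother])
    if (!any(ready)) break
    order <- c(order, ped$id[ready])
    placed[ped$id[ready]] <- TRUE
  }
  if (length(order) < n)
    abort("pedigree contains an ancestry cycle (individual its own ancestor)")
  order
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders, %d affected)\n",
              nrow(x), sum(is.na(x$father)),
              sum(x$affection == "affected")))
  NextMethod()
}

is_founder <- function(ped) is.na(ped$father)
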