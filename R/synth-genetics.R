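# Synthetic genetics: gene dropping through pedigrees, planted
# runs-of-homozygosity genotype panels, and candidate-variant tables.

#' Specification for gene-drop simulation
#'
#' Forward simulation of a biallelic disease locus linked to a
#' multi-allelic marker through a pedigree: founders draw haplotypes from
#' Hardy-Weinberg / linkage-equilibrium priors, transmissions are
#' Mendelian with recombination `theta` between the loci, and phenotypes
#' are penetrance draws.
#'
#' @param pedigree a [pedigree()].
#' @param q disease (risk) allele frequency in (0,1).
#' @param penetrance probability of affection given 0, 1, 2 risk alleles;
#'   default c(0, 0, 0.99) (recessive, 99% penetrance).
#' @param theta recombination fraction between disease and marker locus.
#' @param marker_allele_freqs marker allele frequencies (sum to 1).
#' @param n_replicates number of independent replicates.
#' @param seed integer seed.
#' @return object of class `pedigree_sim_spec`.
#' @export
pedigree_sim_spec <- function(pedigree, q, penetrance = c(0, 0, 0.99),
                              theta = 0, marker_allele_freqs = c(0.25, 0.25,
                                                                 0.25, 0.25),
                              n_replicates = 1, seed = 1L) {
  stopifnot(inherits(pedigree, "pedigree"))
  check_scalar(q, "q", 0, 1, strict_lower = TRUE)
  if (q >= 1) abort("q must be < 1")
  if (length(penetrance) != 3 || any(penetrance < 0 | penetrance > 1))
    abort("penetrance must be three probabilities in [0,1]")
  check_scalar(theta, "theta", 0, 0.5)
  if (abs(sum(marker_allele_freqs) - 1) > 1e-9)
    abort("marker_allele_freqs must sum to 1 (tolerance 1e-9)")
  structure(list(pedigree = pedigree, q = q, penetrance = penetrance,
                 theta = theta, marker_allele_freqs = marker_allele_freqs,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "pedigree_sim_spec")
}

#' Gene-drop genotypes and phenotypes through a pedigree
#'
#' @param spec a [pedigree_sim_spec()].
#' @return list of `n_replicates` data.frames with columns `id`, `d1`,
#'   `d2` (disease-locus alleles, 1 = wild, 2 = risk), `m1`, `m2` (marker
#'   alleles), `disease_geno` (risk-allele count) and `affected`.
#' @export
gene_drop <- function(spec) {
  stopifnot(inherits(spec, "pedigree_sim_spec"))
  ped <- spec$pedigree
  ord <- topo_order(ped)
  idx <- match(ord, ped$id)
  n <- nrow(ped)
  m_alleles <- length(spec$marker_allele_freqs)
  with_seed(spec$seed, 404L, {
    lapply(seq_len(spec$n_replicates), function(rep_i) {
      d <- matrix(0L, n, 2); mk <- matrix(0L, n, 2)
      for (i in idx) {
        if (is.na(ped$father[i])) {
          d[i, ] <- 1L + (stats::runif(2) < spec$q)
          mk[i, ] <- sample.int(m_alleles, 2, replace = TRUE,
                                prob = spec$marker_allele_freqs)
        } else {
          fa <- match(ped$father[i], ped$id)
          mo <- match(ped$mother[i], ped$id)
          for (p in 1:2) {
            par <- if (p == 1) fa else mo
            pick <- sample.int(2, 1)           # haplotype entering meiosis
            other <- 3L - pick
            recomb <- stats::runif(1) < spec$theta
            d[i, p] <- d[par, pick]
            mk[i, p] <- if (recomb) mk[par, other] else mk[par, pick]
          }
        }
      }
      dc <- rowSums(d == 2L)
      affected <- stats::runif(n) < spec$penetrance[dc + 1]
      data.frame(id = ped$id, d1 = d[, 1], d2 = d[, 2],
                 m1 = mk[, 1], m2 = mk[, 2],
                 disease_geno = dc, affected = affected,
                 stringsAsFactors = FALSE)
    })
  })
}

#' Genotype panel with a planted shared homozygous run
#'
#' Builds a marker map and genotype matrix in which every affected
#' individual is homozygous for the same allele across a chosen interval
#' (emulating autozygosity around a recessive disease locus), unaffected
#' individuals are heterozygous there, and genotypes elsewhere are drawn
#' independently from a multi-allelic frequency model.
#'
#' @param n_markers number of markers on the (single) chromosome.
#' @param chrom chromosome label.
#' @param span_cM total map length in cM; markers are evenly spaced.
#' @param affected_ids,unaffected_ids individual ids.
#' @param run_start_cM,run_end_cM the planted interval (NULL for none).
#' @param n_alleles marker alleles, uniform frequencies (default 4).
#' @param seed integer seed.
#' @return list with `map` (marker, chrom, cM) and `genotypes` (character
#'   matrix markers x individuals, entries "a/b").
#' @export
generate_roh_genotypes <- function(n_markers = 60, chrom = "2",
                                   span_cM = 60,
                                   affected_ids, unaffected_ids = character(0),
                                   run_start_cM = NULL, run_end_cM = NULL,
                                   n_alleles = 4, seed = 1L) {
  ids <- c(affected_ids, unaffected_ids)
  with_seed(seed, 505L, {
    cM <- seq(0, span_cM, length.out = n_markers)
    map <- data.frame(marker = sprintf("M%03d", seq_len(n_markers)),
                      chrom = chrom, cM = cM, stringsAsFactors = FALSE)
    geno <- matrix("", n_markers, length(ids),
                   dimnames = list(map$marker, ids))
    for (j in seq_along(ids)) {
      a1 <- sample.int(n_alleles, n_markers, replace = TRUE)
      a2 <- sample.int(n_alleles, n_markers, replace = TRUE)
      geno[, j] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    }
    if (!is.null(run_start_cM)) {
      inrun <- cM >= run_start_cM & cM <= run_end_cM
      for (id in affected_ids) geno[inrun, id] <- "1/1"
      for (id in unaffected_ids) geno[inrun, id] <- "1/2"
    }
    list(map = map, genotypes = geno)
  })
}

#' Specification for a synthetic candidate-variant table
#'
#' @param n_variants total variants (>= 2).
#' @param interval list with `chrom`, `start_cM`, `end_cM`: the linkage
#'   interval containing the causal variant.
#' @param causal_index row index of the planted causal variant (default:
#'   drawn at random).
#' @param af_shape1,af_shape2 Beta parameters for decoy population allele
#'   frequencies.
#' @param seed integer seed.
#' @return object of class `variant_sim_spec`.
#' @export
variant_sim_spec <- function(n_variants = 100,
                             interval = list(chrom = "2", start_cM = 20,
                                             end_cM = 29.4),
                             causal_index = NULL,
                             af_shape1 = 0.3, af_shape2 = 3,
                             seed = 1L) {
  if (n_variants < 2) abort("n_variants must be >= 2")
  structure(list(n_variants = as.integer(n_variants), interval = interval,
                 causal_index = causal_index,
                 af_shape1 = af_shape1, af_shape2 = af_shape2,
                 seed = as.integer(seed)),
            class = "variant_sim_spec")
}

#' Synthetic candidate-variant table with one planted causal variant
#'
#' The causal variant lies in the interval, is homozygous-alt in every
#' affected individual, heterozygous in obligate carriers (parents of
#' affecteds), absent from population databases (frequency 0, zero
#' healthy homozygotes). Every decoy is built to violate at least one of
#' the recessive filter rules (interval membership, homozygosity in
#' affecteds, absence of homozygous unaffecteds, population frequency,
#' healthy homozygotes).
#'
#' @param spec a [variant_sim_spec()].
#' @param ped a [pedigree()].
#' @param phenotypes data.frame `id`, `affected` (logical); defaults to
#'   the pedigree's affection status.
#' @return data.frame: chrom, pos_cM, pos, ref, alt, gene, pop_af,
#'   n_healthy_hom, failure_mode (ground truth; "causal" for the planted
#'   variant), plus one genotype column per pedigree member.
#' @export
generate_variant_table <- function(spec, ped, phenotypes = NULL) {
  stopifnot(inherits(spec, "variant_sim_spec"), inherits(ped, "pedigree"))
  if (is.null(phenotypes))
    phenotypes <- data.frame(id = ped$id,
                             affected = ped$affection == "affected")
  ids <- ped$id
  affected <- phenotypes$id[phenotypes$affected]
  unaffected <- setdiff(ids, affected)
  carriers <- unique(stats::na.omit(c(ped$father[ped$id %in% affected],
                                      ped$mother[ped$id %in% affected])))
  with_seed(spec$seed, 606L, {
    nv <- spec$n_variants
    causal <- spec$causal_index
    if (is.null(causal)) causal <- sample.int(nv, 1)
    int <- spec$interval
    width <- int$end_cM - int$start_cM
    bases <- c("A", "C", "G", "T")
    pos_cM <- stats::runif(nv, int$start_cM, int$end_cM)
    chrom <- rep(int$chrom, nv)
    modes <- sample(c("outside_interval", "not_homozygous_in_affected",
                      "homozygous_in_unaffected", "population_frequency",
                      "healthy_homozygotes"), nv, replace = TRUE)
    if (!length(unaffected))
      modes[modes == "homozygous_in_unaffected"] <- "population_frequency"
    modes[causal] <- "causal"
    pop_af <- stats::rbeta(nv, spec$af_shape1, spec$af_shape2) *
      0.009  # decoys pass the frequency rule unless chosen to fail it
    n_hh <- rep(0L, nv)
    gt <- matrix("0/1", nv, length(ids), dimnames = list(NULL, ids))
    gt[, setdiff(unaffected, carriers)] <- "0/0"
    for (id in affected) gt[, id] <- "1/1"
    for (id in carriers) gt[, id] <- "0/1"
    for (v in seq_len(nv)) {
      switch(modes[v],
        causal = {
          pop_af[v] <- 0; n_hh[v] <- 0L
        },
        outside_interval = {
          pos_cM[v] <- if (stats::runif(1) < 0.5)
            int$start_cM - stats::runif(1, 0.1, width)
          else int$end_cM + stats::runif(1, 0.1, width)
        },
        not_homozygous_in_affected = {
          gt[v, affected[sample.int(length(affected), 1)]] <- "0/1"
        },
        homozygous_in_unaffected = {
          gt[v, unaffected[sample.int(length(unaffected), 1)]] <- "1/1"
        },
        population_frequency = {
          pop_af[v] <- stats::runif(1, 0.02, 1)
        },
        healthy_homozygotes = {
          n_hh[v] <- sample.int(20, 1)
        })
    }
    ra <- t(vapply(seq_len(nv), function(i) sample(bases, 2), character(2)))
    out <- data.frame(chrom = chrom, pos_cM = pos_cM,
                      pos = as.integer(round(pos_cM * 1e6)),
                      ref = ra[, 1], alt = ra[, 2],
                      gene = sprintf("GENE%03d", seq_len(nv)),
                      pop_af = pop_af, n_healthy_hom = n_hh,
                      failure_mode = modes,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(gt, stringsAsFactors = FALSE))
  })
}
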