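# Exact two-locus pedigree likelihood, two-point Lod scores, shared
# runs-of-homozygosity, and recessive candidate-variant filtering.
#
# The likelihood model: a biallelic disease locus (risk-allele frequency
# q, penetrance by risk-allele count) linked at recombination fraction
# theta to a codominant multi-allelic marker. Founders draw haplotypes
# from Hardy-Weinberg / linkage-equilibrium priors; transmissions are
# Mendelian with recombination; phenotypes are penetrance draws. The
# joint likelihood of observed phenotypes and marker genotypes is summed
# exactly over all unobserved two-locus (phased, unordered) genotypes by
# variable elimination on the pedigree graph, which handles the marriage
# loops of consanguineous families without loop-breaking approximations.

#' Recessive linkage model
#'
#' @param q disease (risk) allele frequency, in (0,1). Rare-disease
#'   analyses conventionally assume 0.01 or 0.001; 0.001 is the default.
#' @param penetrance probability of being affected given 0, 1, 2 copies
#'   of the risk allele; default c(0, 0, 0.99) (recessive, 99%
#'   penetrance, no phenocopies).
#' @param theta_grid recombination fractions at which Lod scores are
#'   reported.
#' @param marker_allele_freqs optional marker allele frequency vector
#'   (must sum to 1); defaults to uniform over the alleles observed in
#'   the genotype data.
#' @return object of class `linkage_model`.
#' @export
linkage_model <- function(q = 0.001, penetrance = c(0, 0, 0.99),
                          theta_grid = c(0, 0.01, 0.05, 0.10, 0.20,
                                         0.30, 0.40),
                          marker_allele_freqs = NULL) {
  check_scalar(q, "q", 0, 1, strict_lower = TRUE)
  if (q >= 1) abort("q must be < 1")
  if (length(penetrance) != 3 || any(penetrance < 0 | penetrance > 1))
    abort("penetrance must be three probabilities in [0,1]")
  if (any(theta_grid < 0 | theta_grid > 0.5))
    abort("theta_grid values must lie in [0, 0.5]")
  if (!is.null(marker_allele_freqs)) {
    if (abs(sum(marker_allele_freqs) - 1) > 1e-9)
      abort("marker_allele_freqs must sum to 1")
    if (any(marker_allele_freqs < 0))
      abort("marker_allele_freqs must be nonnegative")
  }
  structure(list(q = q, penetrance = penetrance, theta_grid = theta_grid,
                 marker_allele_freqs = marker_allele_freqs),
            class = "linkage_model")
}

# --- state space -----------------------------------------------------------
# haplotype h = (d, a): d in {1 = wild, 2 = risk}, a in 1..m marker alleles;
# individual state = unordered pair of haplotypes.
two_locus_states <- function(m) {
  H <- 2L * m
  h_d <- rep(1:2, each = m)
  h_a <- rep(seq_len(m), times = 2)
  pairs <- which(upper.tri(matrix(0, H, H), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("h1", "h2")
  list(m = m, H = H, h_d = h_d, h_a = h_a, pairs = pairs,
       S = nrow(pairs),
       disease_count = (h_d[pairs[, 1]] == 2) + (h_d[pairs[, 2]] == 2),
       marker1 = pmin(h_a[pairs[, 1]], h_a[pairs[, 2]]),
       marker2 = pmax(h_a[pairs[, 1]], h_a[pairs[, 2]]))
}

# founder Hardy-Weinberg prior over states
founder_prior <- function(st, q, pa) {
  ph <- ifelse(st$h_d == 2, q, 1 - q) * pa[st$h_a]
  p <- ph[st$pairs[, 1]] * ph[st$pairs[, 2]]
  p * ifelse(st$pairs[, 1] != st$pairs[, 2], 2, 1)
}

# gamete distribution per state: S x H matrix of P(gamete h | parent state)
gamete_matrix <- function(st, theta) {
  hap_index <- function(d, a) (d - 1L) * st$m + a
  G <- matrix(0, st$S, st$H)
  h1 <- st$pairs[, 1]; h2 <- st$pairs[, 2]
  add <- function(col_idx, p) {
    for (s in seq_len(st$S)) G[s, col_idx[s]] <<- G[s, col_idx[s]] + p
  }
  add(h1, (1 - theta) / 2)
  add(h2, (1 - theta) / 2)
  # recombinants: disease allele of one haplotype, marker of the other
  r1 <- hap_index(st$h_d[h1], st$h_a[h2])
  r2 <- hap_index(st$h_d[h2], st$h_a[h1])
  add(r1, theta / 2)
  add(r2, theta / 2)
  G
}

# transmission factor over restricted domains: array [|c|, |f|, |m|]
transmission_factor <- function(st, G, dom_c, dom_f, dom_m) {
  gF <- G[dom_f, , drop = FALSE]   # |f| x H
  gM <- G[dom_m, , drop = FALSE]
  h1 <- st$pairs[dom_c, 1]; h2 <- st$pairs[dom_c, 2]
  out <- array(0, c(length(dom_c), length(dom_f), length(dom_m)))
  for (ci in seq_along(dom_c)) {
    a <- h1[ci]; b <- h2[ci]
    m1 <- outer(gF[, a], gM[, b])
    if (a != b) m1 <- m1 + outer(gF[, b], gM[, a])
    out[ci, , ] <- aperm(m1, c(1, 2))
  }
  aperm(out, c(1, 2, 3))
}

# --- generic factors -------------------------------------------------------
lin_index <- function(dims, coords) {
  # coords: matrix n x k of 1-based coordinates -> linear indices
  stride <- cumprod(c(1, dims[-length(dims)]))
  as.vector(1 + (coords - 1) %*% stride)
}

factor_product <- function(f1, f2, dim_of) {
  vars <- union(f1$vars, f2$vars)
  dims <- dim_of[vars]
  total <- prod(dims)
  coords <- arrayInd(seq_len(total), .dim = dims)
  v1 <- f1$tab[lin_index(dim_of[f1$vars],
                         coords[, match(f1$vars, vars), drop = FALSE])]
  v2 <- f2$tab[lin_index(dim_of[f2$vars],
                         coords[, match(f2$vars, vars), drop = FALSE])]
  list(vars = vars, tab = array(v1 * v2, dim = dims))
}

factor_sum_out <- function(f, v) {
  pos <- match(v, f$vars)
  nv <- length(f$vars)
  if (nv == 1) return(list(vars = integer(0), tab = sum(f$tab)))
  perm <- c(setdiff(seq_len(nv), pos), pos)
  tb <- aperm(f$tab, perm)
  d <- dim(tb)
  tb <- matrix(tb, ncol = d[length(d)])
  list(vars = f$vars[perm[-nv]],
       tab = array(rowSums(tb), dim = d[-length(d)]))
}

# --- likelihood ------------------------------------------------------------

# common setup shared by both summation methods
likelihood_setup <- function(ped, genotypes, model, theta) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- ped$id
  g <- genotypes[match(ids, genotypes$id), , drop = FALSE]
  pa <- model$marker_allele_freqs
  if (is.null(pa)) {
    # uniform prior over the alleles observed in the data
    alleles <- sort(unique(stats::na.omit(c(g$a1, g$a2))))
    if (!length(alleles)) alleles <- 1L
    pa <- rep(1 / length(alleles), length(alleles))
    code <- function(x) match(x, alleles)
  } else {
    # explicit frequencies: allele labels are indices 1..m
    obs <- stats::na.omit(c(g$a1, g$a2))
    if (length(obs) && (any(obs < 1) || any(obs > length(pa))))
      abort("observed marker alleles outside 1..%d (marker_allele_freqs)",
            length(pa))
    code <- function(x) as.integer(x)
  }
  m <- length(pa)
  st <- two_locus_states(m)
  prior <- founder_prior(st, model$q, pa)
  G <- gamete_matrix(st, theta)

  n <- length(ids)
  dom <- vector("list", n)
  unary <- vector("list", n)
  pen <- model$penetrance
  for (i in seq_len(n)) {
    a1 <- code(g$a1[i]); a2 <- code(g$a2[i])
    if (!is.na(a1) && !is.na(a2)) {
      lo <- min(a1, a2); hi <- max(a1, a2)
      dom[[i]] <- which(st$marker1 == lo & st$marker2 == hi)
    } else {
      dom[[i]] <- seq_len(st$S)
    }
    u <- if (is.na(ped$father[i])) prior[dom[[i]]]
         else rep(1, length(dom[[i]]))
    dc <- st$disease_count[dom[[i]]]
    u <- u * switch(ped$affection[i],
                    affected = pen[dc + 1],
                    unaffected = 1 - pen[dc + 1],
                    unknown = rep(1, length(dc)))
    unary[[i]] <- u
    if (all(u == 0)) return(list(zero = TRUE))
  }
  trips <- which(!is.na(ped$father))
  list(zero = FALSE, ids = ids, st = st, G = G, dom = dom, unary = unary,
       trips = trips,
       fa = match(ped$father, ids), mo = match(ped$mother, ids))
}

#' Exact pedigree likelihood at one recombination fraction
#'
#' Joint likelihood of the observed phenotypes and marker genotypes given
#' the pedigree and linkage model, summed exactly over unobserved
#' two-locus genotypes. `method = "elimination"` (default) contracts the
#' pedigree factor graph by greedy variable elimination (exact also on
#' looped, consanguineous pedigrees); `method = "enumeration"` sums over
#' every genotype configuration directly and exists as an independent
#' cross-check, bounded by `max_states` visited configurations.
#'
#' @param ped a [pedigree()].
#' @param genotypes data.frame with columns `id`, `a1`, `a2`: marker
#'   alleles (any integer/character labels), NA for untyped individuals.
#' @param model a [linkage_model()].
#' @param theta recombination fraction in [0, 0.5].
#' @param method "elimination" or "enumeration".
#' @param max_states enumeration bound (default 1e7).
#' @param log if TRUE return the natural-log likelihood.
#' @return the likelihood (or log-likelihood); 0 (-Inf) for Mendelian
#'   inconsistency.
#' @export
pedigree_likelihood <- function(ped, genotypes, model, theta,
                                method = c("elimination", "enumeration"),
                                max_states = 1e7, log = FALSE) {
  method <- match.arg(method)
  check_scalar(theta, "theta", 0, 0.5)
  su <- likelihood_setup(ped, genotypes, model, theta)
  if (su$zero) return(if (log) -Inf else 0)
  ll <- if (method == "elimination") likelihood_eliminate(su)
        else likelihood_enumerate(su, max_states)
  if (log) ll else exp(ll)
}

likelihood_eliminate <- function(su) {
  n <- length(su$ids)
  dim_of <- vapply(su$dom, length, integer(1))
  factors <- lapply(seq_len(n), function(i)
    list(vars = i, tab = array(su$unary[[i]], dim = dim_of[i])))
  for (c in su$trips) {
    factors[[length(factors) + 1]] <-
      list(vars = c(c, su$fa[c], su$mo[c]),
           tab = transmission_factor(su$st, su$G, su$dom[[c]],
                                     su$dom[[su$fa[c]]],
                                     su$dom[[su$mo[c]]]))
  }
  logscale <- 0
  remaining <- seq_len(n)
  while (length(remaining)) {
    # greedy: eliminate the variable with the cheapest combined factor
    cost <- vapply(remaining, function(v) {
      vs <- unique(unlist(lapply(factors,
                                 function(f) if (v %in% f$vars) f$vars)))
      prod(dim_of[vs])
    }, numeric(1))
    v <- remaining[which.min(cost)]
    idx <- which(vapply(factors, function(f) v %in% f$vars, logical(1)))
    f <- factors[[idx[1]]]
    if (length(idx) > 1)
      for (j in idx[-1]) f <- factor_product(f, factors[[j]], dim_of)
    f <- factor_sum_out(f, v)
    mx <- max(f$tab)
    if (mx <= 0) return(-Inf)
    f$tab <- f$tab / mx
    logscale <- logscale + log(mx)
    factors <- c(factors[-idx], list(f))
    remaining <- setdiff(remaining, v)
  }
  scalar <- prod(vapply(factors, function(f) as.numeric(f$tab), numeric(1)))
  if (scalar <= 0) return(-Inf)
  logscale + log(scalar)
}

likelihood_enumerate <- function(su, max_states) {
  n <- length(su$ids)
  sizes <- vapply(su$dom, length, numeric(1))
  total <- prod(sizes)
  if (total > max_states)
    abort(paste("enumeration state space (%g) exceeds max_states (%g);",
                "raise the bound or use method='elimination'"),
          total, max_states)
  # precompute triple tables on restricted domains
  ttabs <- lapply(su$trips, function(c)
    transmission_factor(su$st, su$G, su$dom[[c]], su$dom[[su$fa[c]]],
                        su$dom[[su$mo[c]]]))
  stride <- cumprod(c(1, sizes[-n]))
  acc <- 0
  chunk <- 2e5
  for (start in seq(0, total - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, total - 1)
    coords <- matrix(0L, length(idx), n)
    for (i in seq_len(n))
      coords[, i] <- (idx %/% stride[i]) %% sizes[i] + 1L
    val <- rep(1, length(idx))
    for (i in seq_len(n)) val <- val * su$unary[[i]][coords[, i]]
    for (j in seq_along(su$trips)) {
      c <- su$trips[j]
      d <- dim(ttabs[[j]])
      lin <- 1 + (coords[, c] - 1) + d[1] * (coords[, su$fa[c]] - 1) +
        d[1] * d[2] * (coords[, su$mo[c]] - 1)
      val <- val * ttabs[[j]][lin]
    }
    acc <- acc + sum(val)
  }
  if (acc <= 0) return(-Inf)
  log(acc)
}

#' Two-point Lod scores over a recombination-fraction grid
#'
#' Lod(theta) = log10 L(theta) - log10 L(0.5).
#'
#' @inheritParams pedigree_likelihood
#' @param marker_id optional label carried into the result.
#' @return object of class `lod_result`: data.frame `table` (theta, lod),
#'   `theta_hat` (grid argmax, ties to the smallest theta), `marker_id`.
#' @export
two_point_lod <- function(ped, genotypes, model, marker_id = NA,
                          method = "elimination") {
  l_half <- pedigree_likelihood(ped, genotypes, model, 0.5,
                                method = method, log = TRUE)
  lod <- vapply(model$theta_grid, function(th) {
    (pedigree_likelihood(ped, genotypes, model, th,
                         method = method, log = TRUE) - l_half) / log(10)
  }, numeric(1))
  structure(list(table = data.frame(theta = model$theta_grid, lod = lod),
                 theta_hat = model$theta_grid[which.max(lod)],
                 max_lod = max(lod),
                 marker_id = marker_id),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("two-point Lod for marker %s (theta_hat = %g, max = %.4f)\n",
              x$marker_id, x$theta_hat, x$max_lod))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# --- shared runs of homozygosity ------------------------------------------

#' Shared homozygous segments across affected individuals
#'
#' Finds maximal runs of consecutive markers at which every affected
#' individual is homozygous for the same allele (a homozygosity-by-descent
#' proxy), drops runs shorter than `min_cM`, and annotates each surviving
#' run with the unaffected individuals sharing the same homozygous
#' haplotype across the whole span (exclusion evidence).
#'
#' @param map data.frame with columns `marker`, `chrom`, `cM`, ordered by
#'   cM within chromosome (an unordered map is an error).
#' @param genotypes character matrix of genotypes "a/b", rows = markers in
#'   map order, columns named by individual id.
#' @param affected_ids ids that must share homozygosity.
#' @param unaffected_ids ids checked for exclusion evidence.
#' @param min_cM minimum segment length in centiMorgan (default 4, the
#'   conventional homozygosity-mapping threshold).
#' @param identical_allele if FALSE, require only per-individual
#'   homozygosity, not allele identity across individuals.
#' @return data.frame: chrom, start_cM, end_cM, length_cM, n_markers,
#'   allele, shared_by_unaffected (comma-separated ids, "" if none).
#' @export
shared_roh <- function(map, genotypes, affected_ids,
                       unaffected_ids = character(0), min_cM = 4,
                       identical_allele = TRUE) {
  if (!all(c("marker", "chrom", "cM") %in% names(map)))
    abort("map needs columns marker, chrom, cM")
  if (nrow(map) != nrow(genotypes))
    abort("map and genotypes row counts differ")
  for (ch in unique(map$chrom)) {
    if (is.unsorted(map$cM[map$chrom == ch]))
      abort("markers on chromosome %s are not ordered by cM", ch)
  }
  missing <- setdiff(c(affected_ids, unaffected_ids), colnames(genotypes))
  if (length(missing)) abort("no genotypes for individual %s", missing[1])

  split_geno <- function(gt) {
    parts <- strsplit(gt, "/", fixed = TRUE)
    ok <- lengths(parts) == 2
    a1 <- rep(NA_character_, length(gt)); a2 <- a1
    a1[ok] <- vapply(parts[ok], `[`, "", 1)
    a2[ok] <- vapply(parts[ok], `[`, "", 2)
    cbind(a1, a2)
  }
  hom_allele <- function(id) {
    g <- split_geno(genotypes[, id])
    ifelse(!is.na(g[, 1]) & g[, 1] == g[, 2], g[, 1], NA_character_)
  }
  hom <- vapply(affected_ids, hom_allele,
                character(nrow(genotypes)))
  if (is.null(dim(hom))) hom <- matrix(hom, ncol = length(affected_ids))
  all_hom <- rowSums(is.na(hom)) == 0
  if (identical_allele) {
    same <- all_hom & apply(hom, 1, function(r)
      length(unique(r[!is.na(r)])) <= 1)
  } else {
    same <- all_hom
  }

  out <- data.frame()
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    r <- rle(same[rows])
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- rows[start_i[k]]; i2 <- rows[stop_i[k]]
      len <- map$cM[i2] - map$cM[i1]
      if (len < min_cM) next
      allele <- if (identical_allele) unname(hom[i1, 1]) else NA_character_
      sharers <- character(0)
      for (u in unaffected_ids) {
        hu <- hom_allele(u)[i1:i2]
        ha <- hom[i1:i2, 1]
        if (all(!is.na(hu)) &&
            (!identical_allele || all(hu == ha)))
          sharers <- c(sharers, u)
      }
      out <- rbind(out, data.frame(
        chrom = ch, start_cM = map$cM[i1], end_cM = map$cM[i2],
        length_cM = len, n_markers = i2 - i1 + 1L,
        allele = allele,
        shared_by_unaffected = paste(sharers, collapse = ",")))
    }
  }
  out
}

# --- recessive variant filter ---------------------------------------------

#' Filter candidate variants for a recessive disease model
#'
#' Applies, in documented order, the filters used to reduce an exome
#' candidate list under recessive inheritance: (1) the variant lies in the
#' linkage interval; (2) it is homozygous-alt in every affected; (3) it is
#' not homozygous-alt in any unaffected; (4) its population allele
#' frequency is at most `max_pop_af` (missing/unreported passes); (5) its
#' healthy-homozygote count is at most `max_healthy_hom` (missing passes).
#' Each rejected variant is logged with the first rule it fails.
#'
#' @param variants data.frame with columns `chrom`, a position column
#'   (`pos_cM` by default; see `pos_col`), `gene`, `pop_af`,
#'   `n_healthy_hom`, and one genotype column per sample id ("0/0",
#'   "0/1", "1/1", "./.").
#' @param interval list or data.frame row with `chrom`, `start`, `end`
#'   (`start_cM`/`end_cM` also accepted), in the units of `pos_col`.
#' @param affected_ids,unaffected_ids sample id vectors (must be genotype
#'   columns).
#' @param max_pop_af maximum population allele frequency (default 0.01).
#' @param max_healthy_hom maximum healthy homozygote count (default 0).
#' @param pos_col name of the position column (e.g. "pos" for physical
#'   coordinates).
#' @return list: `pass` (surviving rows of `variants`) and `audit`
#'   (data.frame: row, gene, rule with the first failing rule, "pass"
#'   otherwise).
#' @export
filter_variants <- function(variants, interval, affected_ids,
                            unaffected_ids = character(0),
                            max_pop_af = 0.01, max_healthy_hom = 0,
                            pos_col = "pos_cM") {
  if (nrow(variants) == 0)
    return(list(pass = variants, audit = data.frame()))
  missing <- setdiff(c(affected_ids, unaffected_ids), names(variants))
  if (length(missing)) abort("no genotype column for sample %s", missing[1])
  if (!pos_col %in% names(variants))
    abort("variants lack position column '%s'", pos_col)
  int_start <- interval$start %||% interval$start_cM
  int_end <- interval$end %||% interval$end_cM
  rule <- rep("pass", nrow(variants))
  in_int <- variants$chrom == interval$chrom &
    variants[[pos_col]] >= int_start &
    variants[[pos_col]] <= int_end
  rule[!in_int] <- "outside_interval"
  gt <- as.matrix(variants[, affected_ids, drop = FALSE])
  hom_all_aff <- rowSums(gt == "1/1") == length(affected_ids)
  rule[rule == "pass" & !hom_all_aff] <- "not_homozygous_in_affected"
  if (length(unaffected_ids)) {
    gu <- as.matrix(variants[, unaffected_ids, drop = FALSE])
    hom_any_un <- rowSums(gu == "1/1") > 0
    rule[rule == "pass" & hom_any_un] <- "homozygous_in_unaffected"
  }
  af_fail <- !is.na(variants$pop_af) & variants$pop_af > max_pop_af
  rule[rule == "pass" & af_fail] <- "population_frequency"
  hh_fail <- !is.na(variants$n_healthy_hom) &
    variants$n_healthy_hom > max_healthy_hom
  rule[rule == "pass" & hh_fail] <- "healthy_homozygotes"
  list(pass = variants[rule == "pass", , drop = FALSE],
       audit = data.frame(row = seq_len(nrow(variants)),
                          gene = variants$gene, rule = rule))
}
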