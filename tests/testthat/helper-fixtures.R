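# Shared fixtures for the test suite. Everything is generated in code.

# Consanguineous-style pedigree: two founder couples, a first-cousin
# marriage, and a sibship of affected/unaffected children.
cousin_loop_pedigree <- function(n_children = 3,
                                 affection_children = NULL) {
  ids <- c("F1", "M1", "S1", "S2", "C1", "C2", "D1", "D2",
           paste0("E", seq_len(n_children)))
  father <- c(NA, NA, NA, NA, "F1", "F1", "S1", "S2",
              rep("D1", n_children))
  mother <- c(NA, NA, NA, NA, "M1", "M1", "C1", "C2",
              rep("D2", n_children))
  aff <- rep("unknown", length(ids))
  if (!is.null(affection_children))
    aff[9:(8 + n_children)] <- affection_children
  pedigree(id = ids, father = father, mother = mother, affection = aff)
}

# Random pedigree with a first-cousin loop, random phenotypes and fully
# typed markers; used for peeling-vs-enumeration property tests.
random_loop_pedigree_case <- function(seed) {
  set.seed(seed)
  n_children <- sample(1:2, 1)
  aff <- sample(c("affected", "unaffected", "unknown"), n_children,
                replace = TRUE)
  ped <- cousin_loop_pedigree(n_children, aff)
  m <- sample(2:3, 1)
  n <- nrow(ped)
  # drop marker alleles through the pedigree so genotypes are Mendelian
  # consistent (iid genotypes would mostly have zero likelihood)
  a1 <- integer(n); a2 <- integer(n)
  for (id in dcmpheno:::topo_order(ped)) {
    i <- match(id, ped$id)
    if (is.na(ped$father[i])) {
      a1[i] <- sample.int(m, 1); a2[i] <- sample.int(m, 1)
    } else {
      fa <- match(ped$father[i], ped$id)
      mo <- match(ped$mother[i], ped$id)
      a1[i] <- sample(c(a1[fa], a2[fa]), 1)
      a2[i] <- sample(c(a1[mo], a2[mo]), 1)
    }
  }
  geno <- data.frame(id = ped$id, a1 = a1, a2 = a2)
  pa <- stats::runif(m, 0.2, 1); pa <- pa / sum(pa)
  model <- linkage_model(q = stats::runif(1, 0.05, 0.5),
                         penetrance = sort(stats::runif(3)),
                         marker_allele_freqs = pa)
  list(ped = ped, geno = geno, model = model,
       theta = stats::runif(1, 0, 0.5))
}

# Pedigree whose single scoreable meiosis is phase-known and
# nonrecombinant, so Lod(theta) = log10(2 * (1 - theta)) analytically.
phase_known_meiosis_case <- function() {
  list(ped = pedigree(id = c("GF", "GM", "F", "M", "C"),
                      father = c(NA, NA, "GF", NA, "F"),
                      mother = c(NA, NA, "GM", NA, "M"),
                      affection = c("affected", "unaffected", "unaffected",
                                    "unknown", "affected")),
       geno = data.frame(id = c("GF", "GM", "F", "M", "C"),
                         a1 = c(1, 2, 1, 3, 1),
                         a2 = c(1, 2, 2, 3, 3)),
       model = linkage_model(q = 0.3, penetrance = c(0, 0, 1),
                             marker_allele_freqs = c(0.4, 0.3, 0.3)))
}

# Naive per-block exhaustive NCC matcher: the independent oracle for
# block_match_motion (plain loops, cor()-based score).
naive_block_match <- function(A, B, block_px, search_px) {
  nby <- nrow(A) %/% block_px; nbx <- ncol(A) %/% block_px
  dx <- matrix(NA_integer_, nby, nbx); dy <- matrix(NA_integer_, nby, nbx)
  for (i in seq_len(nby)) for (j in seq_len(nbx)) {
    r0 <- (i - 1) * block_px + 1; c0 <- (j - 1) * block_px + 1
    a <- A[r0:(r0 + block_px - 1), c0:(c0 + block_px - 1)]
    if (stats::sd(a) == 0) next
    best <- -Inf
    for (sy in -search_px:search_px) for (sx in -search_px:search_px) {
      rr <- (r0 + sy):(r0 + block_px - 1 + sy)
      cc <- (c0 + sx):(c0 + block_px - 1 + sx)
      if (min(rr) < 1 || max(rr) > nrow(B) ||
          min(cc) < 1 || max(cc) > ncol(B)) next
      b <- B[rr, cc]
      if (stats::sd(b) == 0) next
      score <- stats::cor(as.vector(a), as.vector(b))
      better <- score > best + 1e-12
      tie <- abs(score - best) <= 1e-12 &&
        (sx^2 + sy^2) < (dx[i, j]^2 + dy[i, j]^2)
      if (better || tie) { best <- score; dx[i, j] <- sx; dy[i, j] <- sy }
    }
  }
  list(dx = dx, dy = dy)
}

# Smooth random texture for motion tests.
random_texture <- function(nr, nc, seed, scale = 3) {
  set.seed(seed)
  raw <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- exp(-(-9:9)^2 / (2 * scale^2)); k <- k / sum(k)
  sm <- apply(raw, 2, function(v)
    stats::filter(c(rep(v[1], 9), v, rep(v[nr], 9)), k)[10:(9 + nr)])
  sm <- t(apply(t(sm), 2, function(v)
    stats::filter(c(rep(v[1], 9), v, rep(v[nc], 9)), k)[10:(9 + nc)]))
  100 * (sm - min(sm)) / diff(range(sm)) + 10
}

# Study-style four-candidate variant table (published database
# frequencies), loaded from the package's extdata.
candidate_variants_path <- function() {
  system.file("extdata", "speg_family_candidate_variants.tsv",
              package = "dcmpheno")
}
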