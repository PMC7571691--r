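test_that("founder allele frequency converges to q", {
  # 2500 independent founders = 5000 allele draws at q = 0.5
  n <- 2500
  ped <- pedigree(id = paste0("I", seq_len(n)))
  reps <- gene_drop(pedigree_sim_spec(ped, q = 0.5,
                                      marker_allele_freqs = c(0.5, 0.5),
                                      seed = 1))
  freq <- mean(c(reps[[1]]$d1, reps[[1]]$d2) == 2)
  se <- sqrt(0.25 / (2 * n))
  expect_lt(abs(freq - 0.5), 3 * se)
})

test_that("free recombination decouples marker from disease allele", {
  # doubly informative founder parent; track which alleles the child got
  ped <- pedigree(id = c("F", "M", "C"), father = c(NA, NA, "F"),
                  mother = c(NA, NA, "M"))
  reps <- gene_drop(pedigree_sim_spec(ped, q = 0.5, theta = 0.5,
                                      marker_allele_freqs = c(0.5, 0.5),
                                      n_replicates = 1000, seed = 7))
  # paternal gamete of the child: disease allele d1, marker allele m1
  gam <- t(vapply(reps, function(r) c(r$d1[3], r$m1[3]), numeric(2)))
  tab <- table(gam[, 1], gam[, 2])
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 1e-3)
})

test_that("recombination at theta = 0 preserves parental haplotypes", {
  ped <- pedigree(id = c("F", "M", "C"), father = c(NA, NA, "F"),
                  mother = c(NA, NA, "M"))
  reps <- gene_drop(pedigree_sim_spec(ped, q = 0.5, theta = 0,
                                      marker_allele_freqs = c(0.5, 0.5),
                                      n_replicates = 200, seed = 8))
  for (r in reps) {
    # child's paternal haplotype must be one of the father's haplotypes
    child <- c(r$d1[3], r$m1[3])
    f1 <- c(r$d1[1], r$m1[1]); f2 <- c(r$d2[1], r$m2[1])
    expect_true(identical(child, f1) || identical(child, f2))
  }
})

test_that("one recorded parent is rejected; gene drop is seeded", {
  expect_error(pedigree(id = c("A", "B"), father = c(NA, "A"),
                        mother = c(NA, NA)),
               "exactly one recorded parent")
  ped <- pedigree(id = c("F", "M", "C"), father = c(NA, NA, "F"),
                  mother = c(NA, NA, "M"))
  spec <- pedigree_sim_spec(ped, q = 0.2, n_replicates = 3, seed = 5)
  expect_identical(gene_drop(spec), gene_drop(spec))
})
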