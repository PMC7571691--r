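test_that("a lone typed founder has the Hardy-Weinberg likelihood", {
  ped <- pedigree(id = "A")
  mod <- linkage_model(q = 0.1, marker_allele_freqs = c(0.3, 0.7))
  L <- pedigree_likelihood(ped, data.frame(id = "A", a1 = 1, a2 = 2),
                           mod, 0.1)
  expect_equal(L, 2 * 0.3 * 0.7, tolerance = 1e-12)
  Lhom <- pedigree_likelihood(ped, data.frame(id = "A", a1 = 2, a2 = 2),
                              mod, 0.1)
  expect_equal(Lhom, 0.49, tolerance = 1e-12)
})

test_that("trio likelihood matches hand enumeration", {
  # fully penetrant recessive, affected child, unaffected parents:
  # both parents are obligate carriers, child homozygous:
  # L = [2q(1-q)]^2 * 1/4
  q <- 0.2
  ped <- pedigree(id = c("F", "M", "C"), father = c(NA, NA, "F"),
                  mother = c(NA, NA, "M"),
                  affection = c("unaffected", "unaffected", "affected"))
  mod <- linkage_model(q = q, penetrance = c(0, 0, 1),
                       marker_allele_freqs = 1)
  L <- pedigree_likelihood(ped, data.frame(id = ped$id, a1 = NA, a2 = NA),
                           mod, 0.2)
  expect_equal(L, (2 * q * (1 - q))^2 / 4, tolerance = 1e-12)
})

test_that("elimination equals enumeration on looped pedigrees", {
  for (seed in 1:20) {
    case <- random_loop_pedigree_case(seed)
    le <- pedigree_likelihood(case$ped, case$geno, case$model, case$theta,
                              method = "elimination", log = TRUE)
    ln <- pedigree_likelihood(case$ped, case$geno, case$model, case$theta,
                              method = "enumeration", log = TRUE)
    if (is.infinite(le)) {
      expect_true(is.infinite(ln))
    } else {
      expect_lt(abs(le - ln), 1e-9)
    }
  }
})

test_that("the Lod score vanishes identically at theta = 0.5", {
  for (seed in 21:25) {
    case <- random_loop_pedigree_case(seed)
    mod <- case$model
    mod$theta_grid <- c(0.1, 0.5)
    lr <- two_point_lod(case$ped, case$geno, mod)
    l05 <- lr$table$lod[lr$table$theta == 0.5]
    if (is.finite(l05)) expect_lt(abs(l05), 1e-9)
  }
})

test_that("a phase-known nonrecombinant meiosis gives Lod(0) = log10 2", {
  case <- phase_known_meiosis_case()
  lr <- two_point_lod(case$ped, case$geno, case$model)
  expect_equal(lr$table$lod,
               log10(2 * (1 - case$model$theta_grid)),
               tolerance = 1e-9)
  expect_equal(lr$table$lod[1], log10(2), tolerance = 1e-12)
  expect_equal(lr$theta_hat, 0)
})

test_that("the Lod curve is smooth on a refined theta grid", {
  case <- phase_known_meiosis_case()
  mod <- case$model
  mod$theta_grid <- seq(0, 0.5, by = 0.01)
  lr <- two_point_lod(case$ped, case$geno, mod)
  expect_true(all(abs(diff(lr$table$lod)) < 0.05))
})

test_that("enumeration enforces its state bound", {
  case <- random_loop_pedigree_case(30)
  geno <- case$geno
  geno$a1 <- NA; geno$a2 <- NA   # untyped: full state space
  expect_error(pedigree_likelihood(case$ped, geno, case$model, 0.1,
                                   method = "enumeration",
                                   max_states = 1e3),
               "max_states")
})

test_that("planted shared homozygous runs are found at the cM threshold", {
  aff <- c("P1", "P2", "P3"); un <- c("U1", "U2")
  rg <- generate_roh_genotypes(n_markers = 61, span_cM = 60,
                               affected_ids = aff, unaffected_ids = un,
                               run_start_cM = 20, run_end_cM = 30,
                               seed = 5)
  seg <- shared_roh(rg$map, rg$genotypes, aff, un)
  expect_equal(nrow(seg), 1)
  spacing <- 1   # markers every 1 cM
  expect_lte(abs(seg$start_cM - 20), spacing)
  expect_lte(abs(seg$end_cM - 30), spacing)
  expect_equal(seg$shared_by_unaffected, "")   # unaffecteds are 1/2 there

  short <- generate_roh_genotypes(n_markers = 61, span_cM = 60,
                                  affected_ids = aff,
                                  run_start_cM = 20, run_end_cM = 23,
                                  seed = 6)
  expect_equal(nrow(shared_roh(short$map, short$genotypes, aff)), 0)
})

test_that("all-heterozygous genotypes yield no shared segment", {
  map <- data.frame(marker = paste0("M", 1:20), chrom = "1", cM = 1:20)
  g <- matrix("1/2", 20, 2, dimnames = list(map$marker, c("P1", "P2")))
  expect_equal(nrow(shared_roh(map, g, c("P1", "P2"))), 0)
})

test_that("segments survive marker permutation after sorting", {
  aff <- c("P1", "P2")
  rg <- generate_roh_genotypes(n_markers = 40, span_cM = 40,
                               affected_ids = aff,
                               run_start_cM = 10, run_end_cM = 22,
                               seed = 9)
  base <- shared_roh(rg$map, rg$genotypes, aff)
  set.seed(1)
  perm <- sample(nrow(rg$map))
  map2 <- rg$map[perm, ]; g2 <- rg$genotypes[perm, , drop = FALSE]
  expect_error(shared_roh(map2, g2, aff), "not ordered")
  ord <- order(map2$cM)
  expect_equal(shared_roh(map2[ord, ], g2[ord, , drop = FALSE], aff),
               base, ignore_attr = TRUE)
})

test_that("variant filtering is order-independent with audited rules", {
  ped <- pedigree(id = c("F1", "M1", "P1", "P2"),
                  father = c(NA, NA, "F1", "F1"),
                  mother = c(NA, NA, "M1", "M1"),
                  affection = c("unaffected", "unaffected", "affected",
                                "affected"))
  spec <- variant_sim_spec(n_variants = 50, seed = 13)
  vt <- generate_variant_table(spec, ped)
  res <- filter_variants(vt, spec$interval, c("P1", "P2"),
                         c("F1", "M1"))
  set.seed(2)
  perm <- sample(nrow(vt))
  res2 <- filter_variants(vt[perm, ], spec$interval, c("P1", "P2"),
                          c("F1", "M1"))
  expect_setequal(res$pass$gene, res2$pass$gene)

  # first-failing rule attribution in documented order
  v <- vt[1, ]
  v$pos_cM <- spec$interval$end_cM + 5       # outside interval
  v$pop_af <- 0.9                            # and common
  res3 <- filter_variants(rbind(v, vt[2, ]), spec$interval,
                          c("P1", "P2"), c("F1", "M1"))
  expect_equal(res3$audit$rule[1], "outside_interval")

  empty <- filter_variants(vt[0, ], spec$interval, c("P1", "P2"))
  expect_equal(nrow(empty$pass), 0)
})
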