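family_ped <- function() {
  pedigree(id = c("F1", "M1", "P1", "P2", "U1"),
           father = c(NA, NA, "F1", "F1", "F1"),
           mother = c(NA, NA, "M1", "M1", "M1"),
           affection = c("unaffected", "unaffected", "affected",
                         "affected", "unaffected"))
}

test_that("exactly the planted causal variant passes every filter", {
  ped <- family_ped()
  spec <- variant_sim_spec(n_variants = 100, seed = 11)
  vt <- generate_variant_table(spec, ped)
  res <- filter_variants(vt, spec$interval,
                         affected_ids = c("P1", "P2"),
                         unaffected_ids = c("F1", "M1", "U1"))
  expect_equal(nrow(res$pass), 1)
  expect_equal(res$pass$failure_mode, "causal")
  expect_equal(res$pass$pop_af, 0)
  expect_equal(res$pass$n_healthy_hom, 0L)
  # audit attributes one first-failing rule to each rejected decoy
  expect_equal(nrow(res$audit), 100)
  expect_equal(sum(res$audit$rule == "pass"), 1)
})

test_that("causal variant construction matches the recessive model", {
  ped <- family_ped()
  vt <- generate_variant_table(variant_sim_spec(n_variants = 10,
                                                causal_index = 4,
                                                seed = 2), ped)
  cv <- vt[4, ]
  expect_equal(cv$failure_mode, "causal")
  expect_true(all(cv[, c("P1", "P2")] == "1/1"))
  expect_true(all(cv[, c("F1", "M1")] == "0/1"))   # obligate carriers
})

test_that("tables are seeded and tiny tables rejected", {
  ped <- family_ped()
  spec <- variant_sim_spec(n_variants = 20, seed = 3)
  expect_identical(generate_variant_table(spec, ped),
                   generate_variant_table(spec, ped))
  expect_error(variant_sim_spec(n_variants = 1), ">= 2")
})
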