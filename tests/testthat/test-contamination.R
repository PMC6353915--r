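test_that("diagnostic positions require difference from every panel member", {
  cons <- "ACGTACGTAC"
  # one panel member equal to the consensus at position 2 -> excluded
  panel <- c(p1 = "ACTTACGTAC", p2 = "ACGTACGTAC")
  d <- find_diagnostic_positions(cons, panel)
  expect_equal(nrow(d), 0)

  # both members differ at position 2
  panel2 <- c(p1 = "ACTTACGTAC", p2 = "ACATACGTAC")
  d2 <- find_diagnostic_positions(cons, panel2)
  expect_equal(d2$position, 2)
  expect_identical(d2$endogenous, "G")
  expect_identical(d2$panel_states, "A,T")

  # panel of copies of the consensus -> nothing diagnostic
  expect_equal(nrow(find_diagnostic_positions(cons, c(a = cons, b = cons))), 0)

  # N in the panel excludes the position
  panelN <- c(p1 = "ACNTACGTAC", p2 = "ACATACGTAC")
  expect_equal(nrow(find_diagnostic_positions(cons, panelN)), 0)

  expect_error(find_diagnostic_positions(cons, character(0)), "panel")
})

test_that("contamination proportion is a per-observation count with Wilson CI", {
  # one diagnostic position at 5: endogenous G, panel state A
  diag <- data.frame(position = 5L, endogenous = "G", panel_states = "A",
                     stringsAsFactors = FALSE)
  # ten single-base observations: 8 endogenous-state, 2 panel-state
  fr <- make_frags(c(rep("G", 8), rep("A", 2)), start = 5)
  est <- estimate_contamination(fr, diag, L = 100, per_library = FALSE)
  expect_equal(est$n_informative, 10)
  expect_equal(est$n_mismatch, 2)
  expect_equal(est$proportion, 0.20)
  ci <- prop.test(2, 10, correct = FALSE)$conf.int
  expect_equal(c(est$ci_lo, est$ci_hi), as.numeric(ci), tolerance = 1e-10)

  # all matching -> 0
  fr0 <- make_frags(rep("G", 5), start = 5)
  expect_equal(estimate_contamination(fr0, diag, 100, FALSE)$proportion, 0)

  # third allele and N excluded from both counts, reported separately
  fr3 <- make_frags(c("G", "A", "C", "N"), start = 5)
  est3 <- estimate_contamination(fr3, diag, 100, FALSE)
  expect_equal(est3$n_informative, 2)
  expect_equal(est3$n_third_allele, 1)

  # no informative observations -> flagged as NA
  frx <- make_frags(rep("C", 3), start = 5)
  estx <- estimate_contamination(frx, diag, 100, FALSE)
  expect_true(is.na(estx$proportion))
})

test_that("a fragment contributes once per covered diagnostic position", {
  diag <- data.frame(position = c(2L, 4L), endogenous = c("G", "C"),
                     panel_states = c("A", "T"), stringsAsFactors = FALSE)
  fr <- make_frags("AAGAC", start = 0)  # covers both: G at 2, C at 4
  est <- estimate_contamination(fr, diag, 50, FALSE)
  expect_equal(est$n_informative, 2)
  expect_equal(est$n_mismatch, 0)
})

test_that("the estimator is invariant to fragment order", {
  ref <- generate_reference(2000, seed = 80)
  h <- generate_haplotypes(ref, 6, 4, 10, seed = 81)
  fr <- simulate_fragments(h, sim_config(2000, contamination_fraction = 0.3,
                                         duplicate_rate = 0, seed = 82))
  diag <- find_diagnostic_positions(h$endogenous, h$panel)
  e1 <- estimate_contamination(fr, diag, 2000)
  e2 <- estimate_contamination(fr[rev(seq_len(nrow(fr))), ], diag, 2000)
  expect_equal(as.data.frame(e1), as.data.frame(e2))
})

test_that("implemented Wilson interval matches prop.test across count grids", {
  for (n in c(5, 40, 500)) for (x in unique(c(0, 1, round(n / 3), n))) {
    expected <- if (n == 0) c(NA, NA) else
      suppressWarnings(as.numeric(prop.test(x, n, correct = FALSE)$conf.int))
    expect_equal(paleomito:::wilson_ci(x, n), expected, tolerance = 1e-10)
  }
})

test_that("deamination filtering lowers the contamination estimate in a mixture", {
  ref <- generate_reference(3000, seed = 90)
  h <- generate_haplotypes(ref, 8, 5, 12, seed = 91)
  fr <- simulate_fragments(h, sim_config(6000, contamination_fraction = 0.4,
                                         duplicate_rate = 0, seed = 92))
  diag <- find_diagnostic_positions(h$endogenous, h$panel)
  contrast <- contamination_before_after(fr, diag, 3000, ref)
  p_all <- contrast$all$proportion[contrast$all$library == "all"]
  p_deam <- contrast$deaminated$proportion[contrast$deaminated$library == "all"]
  expect_lt(p_deam, p_all)
  expect_gt(contrast$reduction, 0.2)  # 40% truth should drop to a few percent

  # zero contamination: both estimates near zero
  fr0 <- simulate_fragments(h, sim_config(3000, contamination_fraction = 0,
                                          duplicate_rate = 0, seed = 93))
  c0 <- contamination_before_after(fr0, diag, 3000, ref)
  expect_lt(c0$all$proportion[c0$all$library == "all"], 0.02)
  expect_lt(c0$deaminated$proportion[c0$deaminated$library == "all"], 0.02)
})

test_that("no enrichment when contaminants are as damaged as endogenous molecules", {
  # switch off terminal elevation entirely: both sources carry only the
  # background rate, so deamination filtering cannot tell them apart
  ref <- generate_reference(3000, seed = 95)
  h <- generate_haplotypes(ref, 6, 4, 10, seed = 96)
  dm <- damage_model(delta_term = 0, delta_bg = 0.05, seq_error = 0)
  fr <- simulate_fragments(h, sim_config(8000, contamination_fraction = 0.4,
                                         duplicate_rate = 0, damage = dm,
                                         seed = 97))
  diag <- find_diagnostic_positions(h$endogenous, h$panel)
  contrast <- contamination_before_after(fr, diag, 3000, ref)
  # no significant reduction: the deaminated-only Wilson CI still covers
  # the all-fragment point estimate
  d <- contrast$deaminated[contrast$deaminated$library == "all", ]
  p_all <- contrast$all$proportion[contrast$all$library == "all"]
  expect_gte(p_all, d$ci_lo)
  expect_lte(p_all, d$ci_hi)
})
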