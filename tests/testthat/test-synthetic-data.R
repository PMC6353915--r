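test_that("generate_reference is deterministic, uniform, and validates length", {
  ref <- generate_reference(L = 16569, seed = 1)
  expect_equal(nchar(ref$sequence), 16569)
  expect_true(ref$circular)
  expect_identical(ref$sequence, generate_reference(L = 16569, seed = 1)$sequence)

  comp <- table(strsplit(generate_reference(2000, seed = 7)$sequence, "")[[1]]) / 2000
  expect_true(all(abs(comp - 0.25) < 0.05))
  expect_setequal(names(comp), c("A", "C", "G", "T"))

  expect_error(generate_reference(999), "1000")
})

test_that("generate_haplotypes plants recoverable private substitutions", {
  ref <- generate_reference(2000, seed = 3)
  h <- generate_haplotypes(ref, k_private = 2, n_panel = 3, panel_div = 5, seed = 9)
  expect_equal(nchar(h$endogenous), 2000)
  expect_true(all(nchar(h$panel) == 2000))

  # exhaustive comparison oracle: positions where endogenous differs from
  # root AND every panel member
  ec <- strsplit(h$endogenous, "")[[1]]
  rc <- strsplit(h$root, "")[[1]]
  pm <- sapply(h$panel, function(s) strsplit(s, "")[[1]])
  oracle <- which(ec != rc & rowSums(pm == ec) == 0) - 1L
  expect_identical(sort(h$private_positions), sort(oracle))
  expect_length(oracle, 2)

  # planted positions are what find_diagnostic_positions recovers
  diag <- find_diagnostic_positions(h$endogenous, h$panel)
  expect_setequal(diag$position, h$private_positions)

  h0 <- generate_haplotypes(ref, k_private = 0, n_panel = 3, panel_div = 5, seed = 1)
  expect_identical(h0$endogenous, h0$root)

  expect_error(generate_haplotypes(ref, k_private = 3000, n_panel = 2,
                                   panel_div = 5, seed = 1), "exceed")
})

test_that("simulated mixture composition follows the contamination fraction", {
  ref <- generate_reference(2000, seed = 1)
  h <- generate_haplotypes(ref, 5, 4, 10, seed = 2)

  fr0 <- simulate_fragments(h, sim_config(200, contamination_fraction = 0,
                                          seed = 4))
  expect_true(all(fr0$truth_label == "endogenous"))

  cfg <- sim_config(1000, contamination_fraction = 0.3, duplicate_rate = 0,
                    seed = 5)
  fr <- simulate_fragments(h, cfg)
  n_cont <- sum(fr$truth_label == "contaminant")
  expect_lt(abs(n_cont - 300), 3 * sqrt(1000 * 0.3 * 0.7))

  # label conservation pre-duplication
  frd <- simulate_fragments(h, sim_config(500, contamination_fraction = 0.4,
                                          duplicate_rate = 0.2, seed = 6))
  expect_equal(sum(!grepl("_dup", frd$id)), 500)
  expect_true(all(frd$truth_label %in% c("endogenous", "contaminant")))
})

test_that("simulation is byte-identical under a fixed config", {
  ref <- generate_reference(1500, seed = 10)
  h <- generate_haplotypes(ref, 4, 3, 8, seed = 11)
  cfg <- sim_config(400, seed = 12, duplicate_rate = 0.15)
  expect_identical(simulate_fragments(h, cfg), simulate_fragments(h, cfg))
})

test_that("terminal damage rate matches the Bernoulli counting oracle", {
  ref <- generate_reference(3000, seed = 20)
  h <- generate_haplotypes(ref, 0, 2, 5, seed = 21)
  dm <- damage_model(delta_term = 0.4, delta_bg = 0, seq_error = 0)
  fr <- simulate_fragments(h, sim_config(3000, contamination_fraction = 0,
                                         duplicate_rate = 0, damage = dm,
                                         seed = 22))
  f <- hand_ct_freq_5p(fr, ref$sequence)
  n_sites <- 0.25 * nrow(fr)  # approximate C-site count at position 1
  expect_lt(abs(f - 0.40), 3 * sqrt(0.4 * 0.6 / n_sites))
})

test_that("endogenous fragments are more damaged than contaminants", {
  ref <- generate_reference(3000, seed = 30)
  h <- generate_haplotypes(ref, 5, 4, 10, seed = 31)
  fr <- simulate_fragments(h, sim_config(10000, contamination_fraction = 0.5,
                                         duplicate_rate = 0, seed = 32))
  endo <- fr[fr$truth_label == "endogenous", ]
  cont <- fr[fr$truth_label == "contaminant", ]
  f_endo <- hand_ct_freq_5p(endo, ref$sequence)
  f_cont <- hand_ct_freq_5p(cont, ref$sequence)
  expect_gt(f_endo, f_cont)
  expect_gt(f_endo, 0.3)
  expect_lt(f_cont, 0.05)
})

test_that("fragments spanning the origin reconstruct against the doubled reference", {
  ref <- generate_reference(1200, seed = 40)
  h <- generate_haplotypes(ref, 0, 1, 0, seed = 41)  # everything equals root
  fr <- simulate_fragments(h, sim_config(2000, contamination_fraction = 0.5,
                                         duplicate_rate = 0,
                                         damage = clean_damage(), seed = 42))
  wrap <- fr[fr$end > 1200, ]
  expect_gt(nrow(wrap), 0)
  doubled <- paste0(ref$sequence, ref$sequence)
  expect_identical(wrap$sequence,
                   substring(doubled, wrap$start + 1, wrap$end))
})

test_that("simulation config validation rejects impossible settings", {
  expect_error(sim_config(contamination_fraction = 1.2), "contamination")
  expect_error(sim_config(length_min = 0), "length_min")
  expect_error(damage_model(delta_term = -0.1), "0, 1")
  expect_error(damage_model(lambda_decay = 0), "lambda")
})
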