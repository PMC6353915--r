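# Reference used in several hand-built cases: C at the start so position 1
# from the 5' end is a C site for + strand fragments starting at 0.

test_that("mismatch profile counts C sites and C->T observations exactly", {
  ref <- "CCAGGTACGTAAGGTTACCA"
  # ten + strand fragments aligned at 0; four read T at position 1
  seqs <- c(rep("TCAGGTACGT", 4), rep("CCAGGTACGT", 6))
  fr <- make_frags(seqs, start = 0)
  prof <- mismatch_profile(fr, ref, n_pos = 5)
  expect_equal(prof$five_prime$sites[1], 10)
  expect_equal(prof$five_prime$ct[1], 4)
  expect_equal(prof$five_prime$frequency[1], 0.40)

  # all identical to the reference -> all frequencies zero
  fr0 <- make_frags(rep(substr(ref, 1, 10), 5), start = 0)
  p0 <- mismatch_profile(fr0, ref, n_pos = 5)
  expect_true(all(p0$five_prime$frequency[p0$five_prime$sites > 0] == 0))
  expect_true(all(p0$three_prime$frequency[p0$three_prime$sites > 0] == 0))

  # non-C reference base at a terminal is excluded from that denominator
  fra <- make_frags("TCAGG", start = 5)  # ref base at 5 is 'T'
  pa <- mismatch_profile(fra, ref, n_pos = 1)
  expect_equal(pa$five_prime$sites[1], 0)
  expect_true(is.na(pa$five_prime$frequency[1]))
})

test_that("minus-strand damage bookkeeping is done in read orientation", {
  ref <- "GGATACCATGACGTATTACG"
  # minus-strand fragment over [0,5): ref G at position 0 is the read's
  # 3' ...  the read 5' end is the right-hand coordinate (position 4)
  # stored reference-forward; ref[1:5] = GGATA; a read-orientation C->T at
  # the 5' terminal appears as G->A at the LEFT end?? no: at position 4
  # the ref base is A; use [0,4): ref GGAT, read = revcomp = ATCC
  # choose window [10,15): ref = CGTAT, read 5' base is ref pos 14 ('T').
  # Simplest: [2,7) ref ATACC -> read revcomp GGTAT, read 5' = complement
  # of ref pos 6 ('C')?? ref pos 6 is 'C', complement G: not a C site.
  # Deliberate construction: read-orientation C at the 5' terminal needs
  # reference G at the fragment's right-hand end.
  # ref positions 10..14 are C G T A T; take [8,13): ref = TGACG, right-
  # hand base ref[12] = 'C'-> no. positions: G0 G1 A2 T3 A4 C5 C6 A7 T8 G9
  # A10 C11 G12 T13 A14 T15 T16 A17 C18 G19. Take [5,10): ref = CCATG,
  # right-hand base ref[9] = G => read 5' site is C. Undamaged stored
  # sequence = CCATG; damaged read has T at its 5' base, i.e. stored A at
  # the right end: CCATA.
  fr <- make_frags(c("CCATA", "CCATG"), start = 5, strand = "-")
  prof <- mismatch_profile(fr, ref, n_pos = 2)
  expect_equal(prof$five_prime$sites[1], 2)
  expect_equal(prof$five_prime$ct[1], 1)
  expect_equal(prof$five_prime$frequency[1], 0.5)
})

test_that("conditioning on one damaged end recovers the endogenous rate in a mixture", {
  ref <- generate_reference(3000, seed = 50)
  h <- generate_haplotypes(ref, 0, 1, 0, seed = 51)
  dm <- damage_model(delta_term = 0.4, delta_bg = 0, seq_error = 0)
  fr <- simulate_fragments(h, sim_config(6000, contamination_fraction = 0.5,
                                         duplicate_rate = 0, damage = dm,
                                         seed = 52))
  # contaminants here are panel copies of the root with zero damage
  uncond <- mismatch_profile(fr, ref)
  cond <- conditional_profile(fr, ref, cond_end = "three_prime",
                              cond_window = 1)
  f_uncond <- uncond$five_prime$frequency[1]
  f_cond <- cond$five_prime$frequency[1]
  expect_lt(abs(f_uncond - 0.20), 0.03)  # mixture algebra: 0.5 * 0.4
  expect_lt(abs(f_cond - 0.40), 0.05)    # conditioning selects damaged molecules
  expect_gt(f_cond, f_uncond)

  # single undamaged source: conditioning set is empty and flagged
  fr_c <- fr[fr$truth_label == "contaminant", ]
  cond0 <- conditional_profile(fr_c, ref, cond_end = "three_prime")
  expect_equal(cond0$n_conditioning, 0)
  expect_true(all(cond0$five_prime$sites == 0))
})

test_that("conditional terminal damage exceeds unconditional across seeds", {
  for (seed in c(101, 102, 103)) {
    ref <- generate_reference(3000, seed = seed)
    h <- generate_haplotypes(ref, 3, 3, 8, seed = seed + 1)
    fr <- simulate_fragments(h, sim_config(10000, contamination_fraction = 0.3,
                                           duplicate_rate = 0, seed = seed + 2))
    uncond <- mismatch_profile(fr, ref)
    cond <- conditional_profile(fr, ref, cond_end = "three_prime")
    expect_gte(cond$five_prime$frequency[1], uncond$five_prime$frequency[1])
  }
})

test_that("deamination flagging inspects exactly the three terminal positions", {
  ref <- "GCCCGTATCCGGATTACCGG"
  # T over ref C at read position 2 -> deaminated
  expect_true(is_deaminated(make_frags("GTCCGTATCC", 0), ref))
  # no mismatches anywhere -> not deaminated
  expect_false(is_deaminated(make_frags("GCCCGTATCC", 0), ref))
  # length-8 fragment over [0,8): ref GCCCGTAT; a C->T at read position 4
  # (index 3) sits outside both 3-base terminal windows -> not deaminated
  expect_false(is_deaminated(make_frags("GCCTGTAT", 0), ref))
})

test_that("deamination filtering is idempotent and enriches endogenous molecules", {
  ref <- generate_reference(2500, seed = 60)
  h <- generate_haplotypes(ref, 3, 3, 8, seed = 61)
  fr <- simulate_fragments(h, sim_config(5000, contamination_fraction = 0.3,
                                         duplicate_rate = 0, seed = 62))
  deam <- filter_deaminated(fr, ref)
  expect_identical(filter_deaminated(deam, ref), deam)
  share_before <- mean(fr$truth_label == "contaminant")
  share_after <- mean(deam$truth_label == "contaminant")
  expect_lt(share_after, share_before)

  undamaged <- simulate_fragments(h, sim_config(200, contamination_fraction = 1,
                                                duplicate_rate = 0,
                                                damage = clean_damage(),
                                                seed = 63))
  expect_equal(nrow(filter_deaminated(undamaged, ref)), 0)
})

test_that("terminal T masking follows the overlapping-window rule and is idempotent", {
  expect_identical(mask_terminal_t("TTACGT", 3), "NNACGN")
  expect_identical(mask_terminal_t("GGACCA", 3), "GGACCA")
  expect_identical(mask_terminal_t("TATTA", 3), "NANNA")  # length 5: all terminal
  expect_identical(mask_terminal_t(mask_terminal_t("TTACGT", 3)),
                   mask_terminal_t("TTACGT", 3))
  # only T is touched
  expect_identical(mask_terminal_t("ACGNA", 3), "ACGNA")

  # minus strand: read-orientation T is stored as A
  fr <- make_frags("ATCGGA", 0, strand = "-")
  masked <- mask_terminal_t(fr, 3)
  expect_identical(masked$sequence, "NTCGGN")
  expect_equal(masked$end - masked$start, nchar(masked$sequence))
})

test_that("terminal damage rate is recovered within 3 SE on labelled data", {
  ref <- generate_reference(3000, seed = 70)
  h <- generate_haplotypes(ref, 0, 1, 0, seed = 71)
  dm <- damage_model(delta_term = 0.4, delta_bg = 0, seq_error = 0)
  fr <- simulate_fragments(h, sim_config(5000, contamination_fraction = 0,
                                         duplicate_rate = 0, damage = dm,
                                         seed = 72))
  prof <- mismatch_profile(fr, ref)
  n_sites <- prof$five_prime$sites[1]
  se <- sqrt(0.4 * 0.6 / n_sites)
  expect_lt(abs(prof$five_prime$frequency[1] - 0.4), 3 * se)
})
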