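# End-to-end orchestration: simulate or ingest fragments, preprocess,
# profile damage, restrict to deaminated fragments, mask, call the
# consensus, estimate contamination at diagnostic positions, and run the
# molecular clock (plus optional radiocarbon calibration), producing one
# structured report.

#' Assemble a pipeline configuration
#'
#' @param input Input description. For simulated input:
#'   `list(type = "sim", L, k_private, n_panel, panel_div, libraries)`
#'   where `libraries` is a list of per-library settings
#'   (`name`, `n_fragments`, `contamination`), plus optional `damage`
#'   (a [damage_model()]) and length/duplicate settings passed to
#'   [sim_config()]. For file input:
#'   `list(type = "tsv"|"sam"|"bam", fragments, ref, panel, root)`
#'   (paths; `root` defaults to `ref`; alignments are ingested via
#'   [read_alignments()]).
#' @param min_len,min_cov,min_support,n_terminal Stage thresholds
#'   (defaults 35, 5, 0.8, 3).
#' @param cond_window Conditioning window for the conditional damage
#'   profile (default 1).
#' @param mu Clock mutation rate, substitutions/site/year (default
#'   2.67e-8).
#' @param mu_interval Optional clock rate interval.
#' @param calibration Optional `list(age, sigma, curve, p)` where `curve`
#'   is a path or a `calibration_curve`.
#' @param patch Optional consensus patch `data.frame` (see
#'   [patch_consensus()]).
#' @param seed Integer seed driving every random stage.
#' @param out_dir Optional run directory; stage artifacts (fragment TSVs,
#'   consensus FASTA, report JSON) are persisted there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(type = "sim"),
                            min_len = 35L, min_cov = 5L, min_support = 0.8,
                            n_terminal = 3L, cond_window = 1L,
                            mu = 2.67e-8, mu_interval = NULL,
                            calibration = NULL, patch = NULL,
                            seed = 1L, out_dir = NULL) {
  if (is.null(input$type)) stop("input$type must be 'sim' or 'tsv'")
  if (input$type == "sim") {
    input$L <- input$L %||% 16569L
    input$k_private <- input$k_private %||% 10L
    input$n_panel <- input$n_panel %||% 311L
    input$panel_div <- input$panel_div %||% 20L
    input$libraries <- input$libraries %||% list(
      list(name = "libB", n_fragments = 10000L, contamination = 0.3))
    input$damage <- input$damage %||% damage_model()
  } else if (input$type %in% c("tsv", "sam", "bam")) {
    for (f in c("fragments", "ref", "panel"))
      if (is.null(input[[f]])) stop("file input requires input$", f)
    input$root <- input$root %||% input$ref
  } else stop("unknown input type: ", input$type)
  structure(list(input = input, min_len = as.integer(min_len),
                 min_cov = as.integer(min_cov), min_support = min_support,
                 n_terminal = as.integer(n_terminal),
                 cond_window = as.integer(cond_window),
                 mu = mu, mu_interval = mu_interval,
                 calibration = calibration, patch = patch,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

terminal_freq <- function(profile, end) {
  df <- profile[[end]]
  df$frequency[1]
}

#' Run the full authentication / consensus / dating pipeline
#'
#' Stages, in order: obtain fragments (simulate with planted truth, or
#' read TSV + FASTA inputs); length-filter (>= `min_len`); fuse
#' coordinate-identical duplicates; per-library damage profiles
#' (terminal and conditional C->T); restrict to deaminated fragments;
#' mask terminal T bases; pileup and threshold consensus (with optional
#' declared-region patch); locate diagnostic positions against the
#' panel; estimate contamination on all vs deaminated-only fragments;
#' count private substitutions against the root and convert to a
#' divergence time; optionally calibrate a radiocarbon measurement.
#'
#' @param config A [pipeline_config()].
#' @return List of class `paleomito_report` with per-library statistics
#'   (`library_table`), `consensus`, `diagnostics`, `contamination`,
#'   `clock`, optional `calibration` and (simulation input only)
#'   `truth_eval` against the planted haplotype.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- config$input
  truth <- NULL
  if (inp$type == "sim") {
    ref <- generate_reference(inp$L, seed = config$seed)
    haps <- generate_haplotypes(ref, inp$k_private, inp$n_panel,
                                inp$panel_div, seed = config$seed + 1L)
    frag_list <- lapply(seq_along(inp$libraries), function(i) {
      lb <- inp$libraries[[i]]
      cfg <- sim_config(n_fragments = lb$n_fragments,
                        contamination_fraction = lb$contamination,
                        damage = inp$damage,
                        duplicate_rate = inp$duplicate_rate %||% 0.1,
                        library = lb$name %||% paste0("lib", i),
                        seed = config$seed + 1L + i)
      simulate_fragments(haps, cfg)
    })
    frags <- do.call(rbind, frag_list)
    ref_seq <- ref$sequence
    panel <- haps$panel
    root <- haps$root
    truth <- haps
  } else {
    frags <- read_alignments(inp$fragments, format = inp$type)
    ref_seq <- read_fasta(inp$ref)[[1]]
    panel <- read_fasta(inp$panel)
    root <- read_fasta(inp$root)[[1]]
  }
  L <- nchar(ref_seq)

  frags <- filter_length(frags, config$min_len)
  unique_frags <- collapse_duplicates(frags)
  deam <- filter_deaminated(unique_frags, ref_seq, config$n_terminal)
  masked <- mask_terminal_t(deam, config$n_terminal)

  pile <- build_pileup(masked, L)
  cons <- call_consensus(pile, config$min_cov, config$min_support)
  if (!is.null(config$patch)) cons <- patch_consensus(cons, config$patch)

  diagnostics <- find_diagnostic_positions(cons, panel)
  contam <- NULL
  if (nrow(diagnostics) > 0)
    contam <- contamination_before_after(unique_frags, diagnostics, L,
                                         ref_seq, config$n_terminal)

  # per-library block mirroring the per-library accounting of the study
  libs <- sort(unique(unique_frags$library))
  lib_rows <- lapply(libs, function(lb) {
    fr <- unique_frags[unique_frags$library == lb, , drop = FALSE]
    dfr <- deam[deam$library == lb, , drop = FALSE]
    prof <- mismatch_profile(fr, ref_seq)
    cond5 <- conditional_profile(fr, ref_seq, "three_prime", config$cond_window)
    cond3 <- conditional_profile(fr, ref_seq, "five_prime", config$cond_window)
    geta <- function(est, col) {
      if (is.null(est)) return(NA_real_)
      v <- est[[col]][est$library == lb]
      if (length(v) == 0) NA_real_ else v
    }
    data.frame(
      library = lb,
      n_unique_fragments = nrow(fr),
      coverage = sum(fr$end - fr$start) / L,
      contamination_pct = 100 * geta(contam$all, "proportion"),
      ct5_pct = 100 * terminal_freq(prof, "five_prime"),
      cond_ct5_pct = 100 * terminal_freq(cond5, "five_prime"),
      ct3_pct = 100 * terminal_freq(prof, "three_prime"),
      cond_ct3_pct = 100 * terminal_freq(cond3, "three_prime"),
      n_deaminated = nrow(dfr),
      coverage_deam = sum(dfr$end - dfr$start) / L,
      contamination_deam_pct = 100 * geta(contam$deaminated, "proportion"),
      stringsAsFactors = FALSE)
  })
  library_table <- do.call(rbind, lib_rows)

  clock_count <- count_private_substitutions(cons, root, panel)
  clock_est <- divergence_time(clock_count, config$mu,
                               conf = 0.95, mu_interval = config$mu_interval)

  calib <- NULL
  if (!is.null(config$calibration)) {
    cl <- config$calibration
    curve <- cl$curve
    if (is.character(curve)) curve <- read_calibration_curve(curve)
    calib <- calibrate_c14(cl$age, cl$sigma, curve, cl$p %||% 0.954)
  }

  truth_eval <- NULL
  if (!is.null(truth)) {
    cmp <- compare_consensus(cons, truth$endogenous)
    called_at_priv <- substring(cons$sequence, truth$private_positions + 1L,
                                truth$private_positions + 1L)
    truth_eval <- list(
      n_compared = cmp$n_compared,
      n_mismatch = nrow(cmp$mismatches),
      accuracy = 1 - nrow(cmp$mismatches) / max(1, cmp$n_compared),
      private_recovered = sum(called_at_priv == truth$private_states),
      private_total = length(truth$private_positions))
  }

  report <- structure(list(
    library_table = library_table,
    consensus = cons,
    diagnostics = diagnostics,
    contamination = contam,
    clock = list(count = clock_count, estimate = clock_est),
    calibration = calib,
    truth_eval = truth_eval,
    params = config[setdiff(names(config), "out_dir")],
    seed = config$seed), class = "paleomito_report")

  if (!is.null(config$out_dir)) persist_report(report, unique_frags,
                                               masked, config$out_dir)
  report
}

persist_report <- function(report, unique_frags, masked, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fragments_tsv(unique_frags, file.path(out_dir, "unique.tsv"))
  write_fragments_tsv(masked, file.path(out_dir, "masked_deaminated.tsv"))
  write_fasta(stats::setNames(report$consensus$sequence, "consensus"),
              file.path(out_dir, "consensus.fa"))
  jsonlite::write_json(report_as_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# JSON-friendly view of a report (S3 objects flattened to plain lists).
report_as_list <- function(report) {
  cons <- report$consensus
  list(
    seed = report$seed,
    library_table = report$library_table,
    consensus = list(n_called = cons$n_called, L = cons$L,
                     mean_coverage = cons$mean_coverage,
                     heteroplasmy = cons$heteroplasmy),
    diagnostics = report$diagnostics,
    contamination = if (!is.null(report$contamination)) list(
      all = as.data.frame(report$contamination$all),
      deaminated = as.data.frame(report$contamination$deaminated),
      reduction = report$contamination$reduction),
    clock = list(k = report$clock$count$k,
                 L_effective = report$clock$count$L_effective,
                 t_hat = report$clock$estimate$t_hat,
                 lower = report$clock$estimate$lower,
                 upper = report$clock$estimate$upper),
    calibration = if (!is.null(report$calibration)) list(
      age = report$calibration$age, sigma = report$calibration$sigma,
      p = report$calibration$p, hpd = report$calibration$hpd),
    truth_eval = report$truth_eval)
}

#' @export
print.paleomito_report <- function(x, ...) {
  cat("== paleomito pipeline report (seed ", x$seed, ") ==\n", sep = "")
  cat("\nPer-library statistics:\n")
  tab <- x$library_table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) round(v, 1))
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$consensus)
  if (!is.null(x$contamination)) print(x$contamination)
  print(x$clock$estimate)
  if (!is.null(x$calibration)) print(x$calibration)
  if (!is.null(x$truth_eval))
    cat(sprintf("truth: %.3f%% of %d compared positions correct; %d/%d private substitutions recovered\n",
                100 * x$truth_eval$accuracy, x$truth_eval$n_compared,
                x$truth_eval$private_recovered, x$truth_eval$private_total))
  invisible(x)
}
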