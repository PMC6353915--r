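# Present-day contamination estimation from diagnostic positions: sites
# where the specimen's consensus differs from every member of a
# present-day comparison panel. Fragments carrying the panel state there
# are counted as contamination.

#' Find positions diagnostic of the endogenous lineage
#'
#' A position is diagnostic when the consensus is called (non-N) and its
#' base differs from the state of EVERY panel member. Positions where the
#' consensus or any panel member is `N` are excluded.
#'
#' @param consensus `consensus_sequence` (or character scalar).
#' @param panel Named character vector of panel haplotypes, each the same
#'   length as the consensus.
#' @return `data.frame` with 0-based `position`, `endogenous` (consensus
#'   state) and `panel_states` (comma-separated states seen in the panel).
#' @export
find_diagnostic_positions <- function(consensus, panel) {
  if (length(panel) == 0) stop("panel must contain at least one haplotype")
  cons <- as_consensus_string(consensus)
  L <- nchar(cons)
  if (any(nchar(panel) != L))
    stop("panel haplotypes must have the same length as the consensus")
  cv <- utf8ToInt(cons)
  pm <- matrix(utf8ToInt(paste(panel, collapse = "")), nrow = L)
  any_n <- rowSums(pm == CHR_N) > 0
  matches <- rowSums(pm == cv) > 0
  diag <- which(cv != CHR_N & !any_n & !matches)
  states <- vapply(diag, function(i)
    paste(sort(unique(intToUtf8(pm[i, ], multiple = TRUE))), collapse = ","),
    character(1))
  data.frame(position = diag - 1L,
             endogenous = intToUtf8(cv[diag], multiple = TRUE) %||% character(0),
             panel_states = states, stringsAsFactors = FALSE)
}

#' Estimate present-day contamination at diagnostic positions
#'
#' Each (fragment, covered diagnostic position) pair is one observation:
#' a fragment contributes once per diagnostic position it covers.
#' Observations matching a panel state are mismatches (contamination
#' evidence); observations matching the endogenous state are matches.
#' `N` bases and third alleles (neither endogenous nor panel state) are
#' excluded from both counts and reported separately as putative
#' errors/damage. The proportion of mismatching observations estimates
#' the contaminant fraction; a Wilson 95% interval is attached.
#'
#' @param frags Fragment `data.frame`.
#' @param diagnostics Output of [find_diagnostic_positions()].
#' @param L Reference length in bases.
#' @param per_library Also report one row per library (default `TRUE`); a
#'   pooled `"all"` row is always present.
#' @return `data.frame` of class `contamination_estimate`: `library`,
#'   `n_informative`, `n_mismatch`, `proportion`, `ci_lo`, `ci_hi`,
#'   `n_third_allele`. Libraries with no informative observations get
#'   `NA` proportions.
#' @export
estimate_contamination <- function(frags, diagnostics, L, per_library = TRUE) {
  if (nrow(diagnostics) == 0) stop("no diagnostic positions supplied")
  validate_fragments(frags)
  bt <- fragment_base_table(frags, L)
  m <- match(bt$refpos, diagnostics$position)
  sel <- which(!is.na(m) & bt$base != CHR_N)
  m <- m[sel]
  obs_base <- intToUtf8(bt$base[sel], multiple = TRUE) %||% character(0)
  endo <- diagnostics$endogenous[m]
  pstates <- strsplit(diagnostics$panel_states, ",", fixed = TRUE)[m]
  is_match <- obs_base == endo
  is_panel <- mapply(function(b, ps) b %in% ps, obs_base, pstates,
                     USE.NAMES = FALSE)
  if (length(sel) == 0) is_panel <- logical(0)
  lib <- frags$library[bt$frag[sel]]
  one <- function(lab, match_v, panel_v) {
    n_inf <- sum(match_v) + sum(panel_v)
    x <- sum(panel_v)
    ci <- wilson_ci(x, n_inf)
    data.frame(library = lab, n_informative = n_inf, n_mismatch = x,
               proportion = if (n_inf > 0) x / n_inf else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2],
               n_third_allele = length(match_v) - n_inf,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (per_library) {
    for (lb in sort(unique(frags$library)))
      rows[[lb]] <- one(lb, is_match[lib == lb], is_panel[lib == lb])
  }
  rows[["all"]] <- one("all", is_match, is_panel)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "positions") <- diagnostics$position
  class(out) <- c("contamination_estimate", "data.frame")
  out
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat("contamination estimate at", length(attr(x, "positions")),
      "diagnostic position(s)\n")
  df <- as.data.frame(x)
  df$proportion <- sprintf("%.1f%%", 100 * df$proportion)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Contamination before and after deamination filtering
#'
#' Runs [estimate_contamination()] on all fragments and again on the
#' deaminated-only subset ([filter_deaminated()]). Because terminal
#' damage is (almost) exclusive to ancient molecules, the deaminated-only
#' estimate is expected to drop sharply when the sample carries
#' present-day contamination.
#'
#' Deamination flags are computed on the unmasked fragments (masking
#' destroys the very T's that identify damage); by default both estimates
#' are then taken on terminal-T-masked fragments, so that
#' deamination-derived T's near fragment ends cannot masquerade as
#' contaminant (or endogenous) states at diagnostic positions.
#'
#' @inheritParams estimate_contamination
#' @param ref Reference sequence used for deamination flagging.
#' @param n_terminal Terminal window for [is_deaminated()] and for
#'   masking (default 3).
#' @param mask Mask terminal T bases before estimating (default `TRUE`).
#' @return List of class `contamination_contrast` with elements `all`,
#'   `deaminated` (both `contamination_estimate`) and `reduction`
#'   (pooled all-fragment minus deaminated-only proportion).
#' @export
contamination_before_after <- function(frags, diagnostics, L, ref,
                                       n_terminal = 3L, per_library = TRUE,
                                       mask = TRUE) {
  deam <- filter_deaminated(frags, ref, n_terminal)
  if (mask) {
    frags <- mask_terminal_t(frags, n_terminal)
    deam <- mask_terminal_t(deam, n_terminal)
  }
  all_est <- estimate_contamination(frags, diagnostics, L, per_library)
  deam_est <- estimate_contamination(deam, diagnostics, L, per_library)
  p_all <- all_est$proportion[all_est$library == "all"]
  p_deam <- deam_est$proportion[deam_est$library == "all"]
  structure(list(all = all_est, deaminated = deam_est,
                 reduction = p_all - p_deam),
            class = "contamination_contrast")
}

#' @export
print.contamination_contrast <- function(x, ...) {
  pa <- x$all$proportion[x$all$library == "all"]
  pd <- x$deaminated$proportion[x$deaminated$library == "all"]
  cat(sprintf("contamination: %.1f%% (all fragments) -> %.1f%% (deaminated only)\n",
              100 * pa, 100 * pd))
  invisible(x)
}
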