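# The authenticity layer: terminal C->T mismatch profiling (unconditional
# and conditional), deamination-based fragment filtering, and terminal T
# masking. All per-end bookkeeping is in READ orientation: the 5' end of
# a minus-strand fragment is its right-hand reference coordinate, and a
# read-orientation C->T appears reference-forward as G->A.

new_damage_profile <- function(five, three, n_fragments, conditional = FALSE,
                               condition = NULL, n_conditioning = NA_integer_) {
  structure(list(five_prime = five, three_prime = three,
                 n_fragments = n_fragments, conditional = conditional,
                 condition = condition, n_conditioning = n_conditioning),
            class = "damage_profile")
}

profile_from_bt <- function(bt, n_pos) {
  cm <- ct_masks(bt)
  end_counts <- function(d) {
    sel <- d < n_pos
    sites <- tabulate(d[cm$site & sel] + 1L, nbins = n_pos)
    ct <- tabulate(d[cm$ct & sel] + 1L, nbins = n_pos)
    data.frame(position = seq_len(n_pos), sites = sites, ct = ct,
               frequency = ifelse(sites > 0, ct / sites, NA_real_))
  }
  list(five = end_counts(bt$d5), three = end_counts(bt$d3))
}

#' C->T mismatch frequencies by distance from each fragment end
#'
#' For each distance `d` from the 5' and from the 3' read end (positions
#' 1..`n_pos`), the denominator counts aligned bases whose reference base
#' is C in read orientation, and the numerator counts those reading T.
#' `N` bases are excluded. Frequencies at uncovered distances are `NA`.
#'
#' @param frags Fragment `data.frame`.
#' @param ref Reference sequence (`mt_genome` or character scalar).
#' @param n_pos Number of terminal positions to profile (default 15).
#' @return An object of class `damage_profile` with `five_prime` and
#'   `three_prime` data frames (`position` is 1-based distance from the
#'   end) of site counts, C->T counts and frequencies.
#' @export
mismatch_profile <- function(frags, ref, n_pos = 15L) {
  ref <- if (inherits(ref, "mt_genome")) ref$sequence else ref
  validate_fragments(frags)
  bt <- fragment_base_table(frags, nchar(ref), ref)
  p <- profile_from_bt(bt, n_pos)
  new_damage_profile(p$five, p$three, nrow(frags))
}

# Per-fragment flag: has >= 1 read-orientation C->T within `window`
# positions of the given end.
has_terminal_ct <- function(bt, n_frag, end = c("five_prime", "three_prime"),
                            window = 1L) {
  end <- match.arg(end)
  d <- if (end == "five_prime") bt$d5 else bt$d3
  cm <- ct_masks(bt)
  hit <- cm$ct & d < window
  tabulate(bt$frag[hit], nbins = n_frag) > 0
}

#' Conditional C->T profile: fragments already damaged at the other end
#'
#' Recomputes the mismatch profile over only those fragments exhibiting at
#' least one C->T within `cond_window` read positions of the conditioning
#' end. In a mixture of damaged endogenous molecules and undamaged
#' contaminants, conditioning enriches for endogenous molecules, so the
#' conditional frequency at the opposite terminal approaches the
#' endogenous damage rate.
#'
#' @inheritParams mismatch_profile
#' @param cond_end Which end to condition on (`"five_prime"` or
#'   `"three_prime"`); the informative frequencies are then at the other
#'   end.
#' @param cond_window Number of terminal positions inspected at the
#'   conditioning end (default 1, the terminal base only).
#' @return A `damage_profile` with `conditional = TRUE`; when no fragment
#'   satisfies the condition all denominators are zero and
#'   `n_conditioning` is 0.
#' @export
conditional_profile <- function(frags, ref, cond_end = c("five_prime", "three_prime"),
                                cond_window = 1L, n_pos = 15L) {
  cond_end <- match.arg(cond_end)
  ref <- if (inherits(ref, "mt_genome")) ref$sequence else ref
  validate_fragments(frags)
  bt <- fragment_base_table(frags, nchar(ref), ref)
  sel <- has_terminal_ct(bt, nrow(frags), cond_end, cond_window)
  sub <- frags[sel, , drop = FALSE]
  btc <- fragment_base_table(sub, nchar(ref), ref)
  p <- profile_from_bt(btc, n_pos)
  new_damage_profile(p$five, p$three, nrow(sub), conditional = TRUE,
                     condition = sprintf(">=1 C->T within %d position(s) of the %s end",
                                         cond_window, sub("_", " ", cond_end)),
                     n_conditioning = sum(sel))
}

#' @export
print.damage_profile <- function(x, n = 5L, ...) {
  kind <- if (isTRUE(x$conditional)) "conditional " else ""
  cat(sprintf("%sC->T damage profile over %d fragments\n", kind, x$n_fragments))
  if (isTRUE(x$conditional))
    cat("  condition: ", x$condition, " (", x$n_conditioning, " fragments)\n", sep = "")
  fmt <- function(df) paste(sprintf("%.1f%%", 100 * df$frequency[seq_len(n)]),
                            collapse = " ")
  cat("  5' positions 1-", n, ": ", fmt(x$five_prime), "\n", sep = "")
  cat("  3' positions 1-", n, ": ", fmt(x$three_prime), "\n", sep = "")
  invisible(x)
}

#' Flag fragments carrying terminal C->T mismatches
#'
#' A fragment is deaminated if at least one of its first `n_terminal` or
#' last `n_terminal` read positions has reference C and reads T (read
#' orientation). For fragments shorter than `2 * n_terminal` the windows
#' overlap; each position is evaluated once.
#'
#' @inheritParams mismatch_profile
#' @param n_terminal Terminal window size at each end (default 3).
#' @return Logical vector, one flag per fragment.
#' @export
is_deaminated <- function(frags, ref, n_terminal = 3L) {
  ref <- if (inherits(ref, "mt_genome")) ref$sequence else ref
  validate_fragments(frags)
  bt <- fragment_base_table(frags, nchar(ref), ref)
  cm <- ct_masks(bt)
  hit <- cm$ct & (bt$d5 < n_terminal | bt$d3 < n_terminal)
  tabulate(bt$frag[hit], nbins = nrow(frags)) > 0
}

#' Restrict a fragment set to deaminated fragments
#'
#' Subsets to fragments flagged by [is_deaminated()]; order is preserved
#' and the operation is idempotent. Because authentic ancient molecules
#' carry terminal damage far more often than present-day contaminants,
#' this enriches strongly for endogenous molecules.
#'
#' @inheritParams is_deaminated
#' @return Filtered fragment `data.frame`.
#' @export
filter_deaminated <- function(frags, ref, n_terminal = 3L) {
  frags[is_deaminated(frags, ref, n_terminal), , drop = FALSE]
}

#' Mask terminal T bases
#'
#' Every `T` among the first `n` and last `n` READ positions becomes `N`
#' (all terminal T's, not only those over a reference C, so that
#' deamination-derived T's cannot leak into the consensus). For a
#' minus-strand fragment the stored reference-forward sequence has its
#' terminal `A` bases masked, which is the same chemical event. Fragments
#' shorter than `2n` have every position treated as terminal.
#'
#' @param x A fragment `data.frame`, or a character vector of
#'   read-orientation sequences.
#' @param n Terminal window size at each end (default 3).
#' @return Object of the same shape as `x` with masked sequences.
#' @export
mask_terminal_t <- function(x, n = 3L) {
  if (is.data.frame(x)) {
    validate_fragments(x)
    x$sequence <- mask_strings(x$sequence, n, x$strand)
    return(x)
  }
  mask_strings(x, n, rep("+", length(x)))
}

mask_strings <- function(seqs, n, strand) {
  if (length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  base <- utf8ToInt(paste(seqs, collapse = ""))
  off <- sequence(lens) - 1L
  len_i <- rep.int(lens, lens)
  terminal <- off < n | off >= len_i - n
  # read-orientation T is stored as A on the minus strand
  target <- ifelse(rep.int(strand, lens) == "+", CHR_T, CHR_A)
  base[terminal & base == target] <- CHR_N
  nseq <- length(seqs)
  substring(intToUtf8(base), cumsum(c(1L, lens[-nseq])), cumsum(lens))
}
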