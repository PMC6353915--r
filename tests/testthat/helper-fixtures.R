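# Small builders used across the suite.

# Fragment table from parallel vectors; end is derived from the sequence.
make_frags <- function(sequence, start, strand = "+", library = "lib1",
                       id = NULL, truth_label = NULL) {
  n <- length(sequence)
  df <- data.frame(
    id = id %||% sprintf("f%03d", seq_len(n)),
    library = rep_len(library, n),
    start = as.integer(start),
    end = as.integer(start + nchar(sequence)),
    strand = rep_len(strand, n),
    sequence = sequence,
    stringsAsFactors = FALSE)
  if (!is.null(truth_label)) df$truth_label <- rep_len(truth_label, n)
  df
}

`%||%` <- paleomito:::`%||%`

# Pileup object built directly from a base-count matrix (rows A,C,G,T).
make_pileup <- function(counts) {
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(counts = counts, L = ncol(counts)), class = "pileup")
}

# Hand-rolled terminal C->T frequency at read position `pos` (1-based
# from the 5' end), independent of the package's profiling code.
hand_ct_freq_5p <- function(frags, ref) {
  doubled <- paste0(ref, ref)
  sites <- 0L; ct <- 0L
  for (i in seq_len(nrow(frags))) {
    rseq <- substring(doubled, frags$start[i] + 1, frags$end[i])
    fseq <- frags$sequence[i]
    if (frags$strand[i] == "-") {
      rseq <- rc1(rseq); fseq <- rc1(fseq)
    }
    if (substr(rseq, 1, 1) == "C" && substr(fseq, 1, 1) != "N") {
      sites <- sites + 1L
      if (substr(fseq, 1, 1) == "T") ct <- ct + 1L
    }
  }
  ct / sites
}

rc1 <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

clean_damage <- function() damage_model(delta_term = 0, lambda_decay = 3,
                                        delta_bg = 0, seq_error = 0)
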