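# Independent oracles, implemented as literally as possible and kept free of
# the package's own code paths.

# Per-base CIGAR expander: advances one base at a time and answers which
# query index (if any) sits on reference position `pos`.
oracle_base_at <- function(start, cigar, seq, pos) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub(".$", "", toks))
  ops <- substr(toks, nchar(toks), nchar(toks))
  ref <- start
  qry <- 1L
  for (i in seq_along(ops)) {
    for (b in seq_len(lens[i])) {
      op <- ops[i]
      if (op %in% c("M", "=", "X")) {
        if (ref == pos)
          return(list(base = substr(seq, qry, qry), index = qry))
        ref <- ref + 1L; qry <- qry + 1L
      } else if (op %in% c("I", "S")) {
        qry <- qry + 1L
      } else if (op %in% c("D", "N")) {
        if (ref == pos) return(list(base = "uncovered", index = NA_integer_))
        ref <- ref + 1L
      }
      # H and P consume nothing
    }
  }
  list(base = "uncovered", index = NA_integer_)
}

# Random alignment: alternating match blocks separated by I/D/N events,
# optionally soft-clipped; returns start, cigar and a random query sequence.
random_alignment <- function() {
  n_events <- sample(0:4, 1)
  ops <- "M"
  for (k in seq_len(n_events)) ops <- c(ops, sample(c("I", "D", "N"), 1), "M")
  if (runif(1) < 0.3) ops <- c("S", ops)
  if (runif(1) < 0.3) ops <- c(ops, "S")
  lens <- sapply(ops, function(o)
    if (o == "N") sample(10:120, 1) else sample(1:30, 1))
  qlen <- sum(lens[ops %in% c("M", "I", "S")])
  list(start = sample(1:500, 1),
       cigar = paste0(lens, ops, collapse = ""),
       seq = paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE),
                   collapse = ""))
}

# Naive full-scan pileup: iterates every record of the BAM, re-applies the
# flag/quality filters literally, locates the site base with the per-base
# expander, and tallies per cell (consensus by explicit per-molecule loop).
naive_pileup <- function(bam, site, min_base_quality = 20,
                         min_mapping_quality = 0, require_cb = TRUE,
                         umi_mode = "consensus", strip_suffix = TRUE) {
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "pos", "cigar", "seq", "qual", "mapq"),
    tag = c("CB", "UB"))
  r <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(r$pos)
  cb_all <- if (is.null(r$tag$CB)) rep(NA_character_, n) else r$tag$CB
  ub_all <- if (is.null(r$tag$UB)) rep(NA_character_, n) else r$tag$UB
  bc <- character(); umi <- character(); base <- character()
  for (i in seq_len(n)) {
    fl <- r$flag[i]
    if (bitwAnd(fl, 4L) > 0) next        # unmapped
    if (bitwAnd(fl, 256L) > 0) next      # secondary
    if (bitwAnd(fl, 2048L) > 0) next     # supplementary
    if (bitwAnd(fl, 512L) > 0) next      # QC fail
    hit <- oracle_base_at(r$pos[i], r$cigar[i], as.character(r$seq[i]),
                          site$pos)
    if (hit$base == "uncovered") next
    q <- as.integer(charToRaw(substr(as.character(r$qual[i]),
                                     hit$index, hit$index))) - 33L
    if (q < min_base_quality) next
    mq <- r$mapq[i]
    if (!is.na(mq) && mq != 255L && mq < min_mapping_quality) next
    if (require_cb && is.na(cb_all[i])) next
    bc <- c(bc, if (is.na(cb_all[i])) "(no-CB)" else
      if (strip_suffix) sub("-[0-9]+$", "", cb_all[i]) else cb_all[i])
    umi <- c(umi, ub_all[i])
    base <- c(base, hit$base)
  }
  if (umi_mode == "consensus") {
    umi[is.na(umi)] <- paste0("#solo", seq_len(sum(is.na(umi))))
    keys <- unique(paste(bc, umi))
    bc2 <- character(); base2 <- character()
    for (k in keys) {
      sel <- paste(bc, umi) == k
      votes <- table(base[sel])
      best <- names(votes)[votes == max(votes)]
      if (length(best) > 1L) next                 # tie: molecule discarded
      bc2 <- c(bc2, bc[sel][1]); base2 <- c(base2, best)
    }
    bc <- bc2; base <- base2
  }
  cells <- sort(unique(bc))
  do.call(rbind, lapply(cells, function(cell) {
    b <- base[bc == cell]
    data.frame(barcode = cell,
               n_ref = sum(b == site$ref),
               n_alt = sum(b == site$alt),
               n_other = sum(b != site$ref & b != site$alt),
               stringsAsFactors = FALSE)
  }))
}

# Literal recovery-curve accumulator: walks k = 1..T, counts set genes among
# the top k at each step, sums the step heights, divides by the ideal area.
brute_auc <- function(ranks, set_idx, top_fraction) {
  n <- length(ranks)
  T <- floor(top_fraction * n)
  in_set <- logical(n)
  in_set[set_idx] <- TRUE
  area <- 0
  ideal <- 0
  s <- sum(in_set)
  for (k in seq_len(T)) {
    hk <- 0
    for (g in seq_len(n)) if (in_set[g] && ranks[g] <= k) hk <- hk + 1
    area <- area + hk
    ideal <- ideal + min(k, s)
  }
  area / ideal
}

# Priority-order oracle for combining per-site labels.
oracle_combine_label <- function(labels) {
  pr <- c(ALT = 1, REF = 2, UNKNOWN = 3)
  names(which.min(pr[labels]))
}
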