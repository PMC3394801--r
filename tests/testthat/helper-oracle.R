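# Brute-force matching oracle: exhaustively enumerates all ordered tuples of
# distinct residues with allowed types and scores them with plain arithmetic,
# independently of the package's pruned search. Only usable on small
# structures.

oracle_best_match <- function(pm, target, cfg = scan_config()) {
  res <- residue_table(target)
  k <- nrow(pm$positions)
  cand <- lapply(pm$allowed, function(al) {
    idx <- which(res$resname %in% names(al))
    # keep residues that actually contain the mapped atom
    keep <- vapply(idx, function(i) {
      atom <- unname(al[res$resname[i]])
      any(target$atoms$chain == res$chain[i] &
            target$atoms$resno == res$resno[i] &
            target$atoms$insert == res$insert[i] &
            target$atoms$name == atom)
    }, logical(1))
    idx[keep]
  })
  if (any(lengths(cand) == 0)) return(NULL)
  tuples <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (r in seq_len(nrow(tuples))) {
    tup <- as.integer(tuples[r, ])
    if (anyDuplicated(tup)) next
    xyz <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      i <- tup[j]
      atom <- unname(pm$allowed[[j]][res$resname[i]])
      row <- target$atoms[target$atoms$chain == res$chain[i] &
                            target$atoms$resno == res$resno[i] &
                            target$atoms$insert == res$insert[i] &
                            target$atoms$name == atom, ][1, ]
      xyz[j, ] <- c(row$x, row$y, row$z)
    }
    ok <- TRUE
    total <- 0
    npair <- 0
    for (p in seq_len(k - 1)) {
      for (q in seq((p + 1), k)) {
        dref <- pm$ref_dist[p, q]
        dtgt <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
        if (abs(dref - dtgt) > cfg$distance_window) { ok <- FALSE; break }
        total <- total + cfg$d_weight * abs(dref - dtgt) / dref
        npair <- npair + 1
      }
      if (!ok) break
    }
    if (!ok) next
    score <- total / (k * (k - 1) / 2)
    if (is.null(best) || score < best$score) {
      best <- list(score = score, residues = res$resno[tup])
    }
  }
  best
}
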