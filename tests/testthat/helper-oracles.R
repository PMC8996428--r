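# Independent oracles used to cross-check the package implementations.

GC <- vqsurvey:::GENETIC_CODE_STD
STOPS <- c("TAA", "TAG", "TGA")

codons_of <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))

# --- NG86 oracle: explicit pathway enumeration, written recursively ---------

oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
    muts <- vapply(alts, function(a) { m <- codon; substr(m, pos, pos) <- a; m },
                   character(1))
    muts <- muts[!muts %in% STOPS]
    if (length(muts) == 0) next
    total <- total + sum(GC[muts] == GC[[codon]]) / length(muts)
  }
  total
}

oracle_pathways <- function(from, to, avoid_stops = TRUE) {
  # returns list of c(sd, nd) for each valid pathway, by recursion
  pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (length(pos) == 0) return(list(c(0, 0)))
  out <- list()
  for (p in pos) {
    step <- from
    substr(step, p, p) <- substr(to, p, p)
    if (avoid_stops && step %in% STOPS) next
    syn_step <- as.integer(GC[[from]] == GC[[step]])
    for (tail in oracle_pathways(step, to, avoid_stops))
      out[[length(out) + 1]] <- c(syn_step, 1 - syn_step) + tail
  }
  out
}

oracle_ng86 <- function(cds_a, cds_b) {
  ca <- codons_of(cds_a); cb <- codons_of(cds_b)
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    paths <- oracle_pathways(ca[i], cb[i])
    if (length(paths) == 0) paths <- oracle_pathways(ca[i], cb[i], avoid_stops = FALSE)
    m <- do.call(rbind, paths)
    Sd <- Sd + mean(m[, 1]); Nd <- Nd + mean(m[, 2])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ps <- if (S == 0) 0 else Sd / S
  list(ka = jc(Nd / N), ks = jc(ps))
}

rand_sense_codons <- function(n) {
  sense <- names(GC)[GC != "*"]
  sample(sense, n, replace = TRUE)
}

# random codon pair with some substitutions, both sequences stop-free
rand_codon_pair <- function(n_codons, n_mut) {
  a <- rand_sense_codons(n_codons)
  b <- a
  sites <- sample(n_codons * 3, min(n_mut, n_codons * 3))
  for (s in sites) {
    ci <- (s - 1) %/% 3 + 1
    pos <- (s - 1) %% 3 + 1
    repeat {
      alt <- sample(c("A", "C", "G", "T"), 1)
      cand <- b[ci]
      substr(cand, pos, pos) <- alt
      if (!cand %in% STOPS) { b[ci] <- cand; break }
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# --- SSR brute-force oracle: per-start block extension ----------------------

oracle_primitive <- function(unit) {
  k <- nchar(unit)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d) next
    if (paste(rep(substr(unit, 1, d), k / d), collapse = "") == unit) return(FALSE)
  }
  TRUE
}

oracle_ssrs <- function(s, thresholds = c(10, 6, 5, 5, 5, 5)) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  rows <- list()
  for (k in 1:6) {
    if (n < 2 * k) next
    idx <- seq_len(n - 2 * k + 1)
    u1 <- substring(s, idx, idx + k - 1)
    u2 <- substring(s, idx + k, idx + 2 * k - 1)
    cand <- idx[u1 == u2 & !grepl("[^ACGT]", u1)]
    for (i in cand) {
      unit <- substring(s, i, i + k - 1)
      if (!oracle_primitive(unit)) next
      # leftmost start of the periodic region
      if (i > 1 && ch[i - 1] == ch[i + k - 1] &&
          ch[i - 1] %in% c("A", "C", "G", "T")) next
      count <- 1
      while (i + (count + 1) * k - 1 <= n &&
             substring(s, i + count * k, i + (count + 1) * k - 1) == unit)
        count <- count + 1
      if (count >= thresholds[k])
        rows[[length(rows) + 1]] <- data.frame(
          motif = unit, repeat_count = count, start = i,
          end = i + count * k - 1, ssr_type = paste0("p", k))
    }
  }
  if (length(rows) == 0)
    return(data.frame(motif = character(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0),
                      ssr_type = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

# --- homoeolog ratio rule oracle (direct case analysis) ---------------------

oracle_ratio <- function(nA, nB, nD) {
  v <- sort(c(nA, nB, nD))
  if (identical(v, c(1L, 1L, 1L))) "TRIAD_1_1_1"
  else if (v[1] == 1 && v[2] == 1 && v[3] > 1) "DUP_n_1_1"
  else if (identical(v[1:2], c(0L, 1L)) && v[3] == 1) "LOSS_1_1_0"
  else if (sum(v) == 1) "ORPHAN"
  else "OTHER"
}
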