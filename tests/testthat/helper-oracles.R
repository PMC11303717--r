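# Independent oracles used across the suite. These deliberately avoid the
# package's own complement operators.

BASES <- c("A", "C", "G", "T")
WC <- c(A = "T", C = "G", G = "C", T = "A")

# base-by-base reverse complement, loop form
revcomp_oracle <- function(s) {
  chars <- strsplit(s, "")[[1]]
  paste(rev(unname(WC[chars])), collapse = "")
}

# per-domain reverse complement, loop form
switchback_oracle <- function(s, domain_length) {
  n <- nchar(s)
  stopifnot(n %% domain_length == 0)
  doms <- substring(s, seq(1, n, domain_length),
                    seq(domain_length, n, domain_length))
  paste(vapply(doms, revcomp_oracle, character(1)), collapse = "")
}

# physically enumerate base-pair opposition in both geometries:
#  - duplex: antiparallel end-to-end, s1[i] opposite s2[n+1-i]
#  - switchback: strands parallel, domain i opposite domain i,
#    locally antiparallel within each domain
classify_oracle <- function(s1, s2, domain_length) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  n <- length(c1)
  dup <- all(WC[c1] == rev(c2))
  nd <- n / domain_length
  per_domain <- integer(nd)
  for (d in seq_len(nd)) {
    off <- (d - 1) * domain_length
    for (j in seq_len(domain_length)) {
      if (WC[c1[off + j]] == c2[off + domain_length + 1 - j])
        per_domain[d] <- per_domain[d] + 1L
    }
  }
  sb <- all(per_domain == domain_length)
  rel <- if (dup && sb) "both" else if (dup) "duplex" else
    if (sb) "switchback" else "none"
  list(relationship = rel, per_domain = per_domain)
}

# quadratic-time tandem-tract finder: for every unit length and start,
# extend while s[k] == s[k + u]; keep maximal tracts with enough copies,
# then apply the documented resolution policy (longest tract first, ties
# to the smaller unit, greedy non-overlap).
brute_force_tandem <- function(seqstr, unit_lengths, min_copies) {
  chars <- strsplit(seqstr, "")[[1]]
  n <- length(chars)
  cand <- list()
  for (u in unit_lengths) {
    i <- 1L
    while (i + u <= n) {
      if (chars[i] == chars[i + u]) {
        j <- i
        while (j + u <= n && chars[j] == chars[j + u]) j <- j + 1L
        run <- j - i            # length of the self-offset match run
        if (run >= (min_copies - 1) * u)
          cand[[length(cand) + 1L]] <-
            data.frame(start = i, end = i + run + u - 1L, unit_length = u)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(cand)) return(data.frame(start = integer(), end = integer(),
                                       unit_length = integer()))
  cand <- do.call(rbind, cand)
  cand$len <- cand$end - cand$start + 1L
  cand <- cand[order(-cand$len, cand$unit_length, cand$start), ]
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    span <- cand$start[k]:cand$end[k]
    if (!any(taken[span])) {
      keep[k] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- cand[keep, c("start", "end", "unit_length")]
  out[order(out$start), , drop = FALSE]
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE))
}

# all 64 reverse-complement-palindromic 6-mers
palindromic_hexamers <- function() {
  halves <- all_kmers(3)
  paste0(halves, vapply(halves, revcomp_oracle, character(1)))
}
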