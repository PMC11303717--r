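#' Canonicalize and validate a DNA sequence
#'
#' Sequences are the universal currency of the package: plain character
#' vectors over the alphabet A/C/G/T, always read 5'->3'. Input is
#' case-insensitive and canonicalized to uppercase. IUPAC ambiguity codes
#' (N, R, Y, ...) are rejected rather than expanded, because switchback
#' pairing is defined on fully specified sequences only.
#'
#' @param x character vector of DNA sequences (5'->3').
#' @return the canonicalized (uppercase) character vector.
#' @examples
#' dna("cagcag")
#' @export
dna <- function(x) {
  if (!is.character(x)) stop("sequence must be a character vector", call. = FALSE)
  x <- toupper(x)
  bad <- gsub("[ACGT]", "", x)
  if (any(nzchar(bad))) {
    offenders <- sort(unique(unlist(strsplit(bad[nzchar(bad)], ""))))
    stop("invalid characters in sequence: ", paste(offenders, collapse = ", "),
         " (only A/C/G/T allowed; ambiguity codes are rejected)", call. = FALSE)
  }
  if (any(!nzchar(x))) stop("sequence must have length >= 1", call. = FALSE)
  x
}

#' Half-turn domain layout
#'
#' The geometry that turns a plain sequence into a switchback candidate:
#' half-turn domains of `domain_length` base pairs (6 bp in B-DNA),
#' `n_domains` of them, plus optional non-pairing terminal caps (a single
#' thymine on each end is the usual anti-aggregation cap). Layouts with 2-4
#' domains are the characterized regime; more domains are accepted but a
#' caveat is messaged, since larger switchbacks tend to aggregate.
#'
#' @param domain_length nucleotides per half-turn domain (default 6).
#' @param n_domains number of half-turn domains (>= 2).
#' @param cap5,cap3 non-pairing terminal sequences ("" for none).
#' @return an object of class `domain_layout`.
#' @examples
#' domain_layout()                       # 6 x 2, no caps
#' domain_layout(cap5 = "T", cap3 = "T") # terminal-thymine capped
#' @export
domain_layout <- function(domain_length = 6L, n_domains = 2L,
                          cap5 = "", cap3 = "") {
  domain_length <- as.integer(domain_length)
  n_domains <- as.integer(n_domains)
  if (is.na(domain_length) || domain_length < 1L)
    stop("domain_length must be a positive integer", call. = FALSE)
  if (is.na(n_domains) || n_domains < 2L)
    stop("n_domains must be an integer >= 2", call. = FALSE)
  if (n_domains > 4L)
    message("layout has ", n_domains,
            " half-turn domains; structures beyond 4 half-turns may aggregate")
  if (nzchar(cap5)) cap5 <- dna(cap5) else cap5 <- ""
  if (nzchar(cap3)) cap3 <- dna(cap3) else cap3 <- ""
  structure(
    list(domain_length = domain_length, n_domains = n_domains,
         cap5 = cap5, cap3 = cap3,
         core_length = domain_length * n_domains),
    class = "domain_layout"
  )
}

#' @export
print.domain_layout <- function(x, ...) {
  caps <- paste0(
    if (nzchar(x$cap5)) paste0("5'-", x$cap5, " ") else "",
    if (nzchar(x$cap3)) paste0(x$cap3, "-3'") else ""
  )
  cat(sprintf("<domain_layout> %d x %d nt (core %d nt)%s\n",
              x$n_domains, x$domain_length, x$core_length,
              if (nzchar(caps)) paste0(", caps ", trimws(caps)) else ""))
  invisible(x)
}

# Strip declared caps and check the residue length against the layout.
layout_core <- function(seq, layout) {
  seq <- dna(seq)
  n5 <- nchar(layout$cap5)
  n3 <- nchar(layout$cap3)
  if (nchar(seq) != layout$core_length + n5 + n3)
    stop("sequence core is ", nchar(seq) - n5 - n3,
         " nt but layout requires ", layout$core_length,
         " nt (", layout$n_domains, " x ", layout$domain_length, ")",
         call. = FALSE)
  if (n5 > 0 && substr(seq, 1L, n5) != layout$cap5)
    stop("5' cap '", layout$cap5, "' not found on sequence", call. = FALSE)
  if (n3 > 0 && substr(seq, nchar(seq) - n3 + 1L, nchar(seq)) != layout$cap3)
    stop("3' cap '", layout$cap3, "' not found on sequence", call. = FALSE)
  substr(seq, n5 + 1L, n5 + layout$core_length)
}

#' Partition a sequence into half-turn domains
#'
#' Strips the layout's caps and cuts the core into `n_domains` contiguous
#' 5'->3' slices of `domain_length` nt each. Concatenating the slices (plus
#' caps) restores the input.
#'
#' @param seq a DNA sequence (character scalar).
#' @param layout a [domain_layout()].
#' @return character vector of domain sequences, 5'->3' order.
#' @examples
#' partition_domains("CAGCAGCAGCAG", domain_layout())
#' @export
partition_domains <- function(seq, layout = domain_layout()) {
  core <- layout_core(seq, layout)
  starts <- seq.int(1L, by = layout$domain_length, length.out = layout$n_domains)
  substring(core, starts, starts + layout$domain_length - 1L)
}

#' Duplex (reverse) complement
#'
#' The partner strand in a conventional antiparallel B-form duplex: the
#' reverse complement, returned 5'->3'. Vectorized.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' duplex_complement("CAGCAGCAGCAG")  # "CTGCTGCTGCTG"
#' @export
duplex_complement <- function(seq) {
  seq <- dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Switchback complement
#'
#' The partner strand in the switchback sense: each half-turn domain is
#' reverse-complemented individually while the domain order is preserved.
#' Equivalently, the duplex complement of the core with its domain order
#' reversed. In the switchback structure the two strands run parallel
#' overall, pairing domain i with domain i (5' ends co-located), while each
#' individual domain is a locally antiparallel B-DNA half-turn.
#'
#' @param seq a DNA sequence (character scalar).
#' @param layout a [domain_layout()].
#' @param keep_caps if `TRUE` (default) the layout's caps are re-attached to
#'   the returned strand; `FALSE` returns the bare core complement.
#' @param register domain pairing register. `"index"` (default) pairs domain
#'   i with domain i; `"reversed"` pairs domain i with domain n+1-i, in
#'   which case the operator coincides with the duplex complement of the
#'   core. For 3- and 4-domain layouts the index-matched register is assumed
#'   to generalize unchanged.
#' @return the switchback complement, 5'->3'.
#' @examples
#' switchback_complement("AAAAAACCCCCC")  # "TTTTTTGGGGGG"
#' @export
switchback_complement <- function(seq, layout = domain_layout(),
                                  keep_caps = TRUE,
                                  register = c("index", "reversed")) {
  register <- match.arg(register)
  doms <- partition_domains(seq, layout)
  rc <- duplex_complement(doms)
  if (register == "reversed") rc <- rev(rc)
  core <- paste(rc, collapse = "")
  if (keep_caps) paste0(layout$cap5, core, layout$cap3) else core
}

# Positionwise match vector of s2 against the reverse complement of s1
# (both plain cores of equal length).
pairwise_matches <- function(s1, s2) {
  strsplit(duplex_complement(s1), "")[[1]] == strsplit(s2, "")[[1]]
}

#' Classify the relationship between two strands
#'
#' Tests whether `s2` is the duplex complement and/or the switchback
#' complement of `s1` on their cores, and reports per-domain detail. A pair
#' can be `"both"`: when every domain of `s1` equals every other in a way
#' that makes the two complements coincide (e.g. short tandem repeats whose
#' unit divides the domain length), the same partner strand serves in either
#' geometry.
#'
#' @param s1,s2 DNA sequences; both cores must partition under `layout`.
#' @param layout a [domain_layout()].
#' @return a `pairing_report` with fields `relationship` (one of `duplex`,
#'   `switchback`, `both`, `none`), `per_domain_matches` (matched base pairs
#'   per domain in the switchback sense), `duplex_matches`, and
#'   `mismatch_positions` (data.frame of domain / in-domain position, in the
#'   switchback sense, 1-based on `s1`).
#' @examples
#' classify_pair("CAGCAGCAGCAG", "CTGCTGCTGCTG")$relationship  # "both"
#' @export
classify_pair <- function(s1, s2, layout = domain_layout()) {
  d1 <- partition_domains(s1, layout)
  d2 <- partition_domains(s2, layout)
  L <- layout$domain_length

  # switchback sense: domain i of s2 against revcomp(domain i of s1)
  per_domain <- integer(length(d1))
  mm <- list()
  for (i in seq_along(d1)) {
    m <- pairwise_matches(d1[i], d2[i])
    per_domain[i] <- sum(m)
    if (any(!m)) {
      # index k of s2's domain faces position L+1-k of s1's domain
      mm[[length(mm) + 1L]] <-
        data.frame(domain = i, position = sort(L + 1L - which(!m)))
    }
  }
  mismatch_positions <- if (length(mm)) do.call(rbind, mm) else
    data.frame(domain = integer(), position = integer())

  core1 <- paste(d1, collapse = "")
  core2 <- paste(d2, collapse = "")
  duplex_matches <- sum(pairwise_matches(core1, core2))

  is_dup <- duplex_matches == nchar(core1)
  is_sb <- all(per_domain == L)
  relationship <- if (is_dup && is_sb) "both" else if (is_dup) "duplex" else
    if (is_sb) "switchback" else "none"

  structure(
    list(relationship = relationship,
         per_domain_matches = per_domain,
         duplex_matches = duplex_matches,
         mismatch_positions = mismatch_positions,
         layout = layout),
    class = "pairing_report"
  )
}

#' @export
print.pairing_report <- function(x, ...) {
  cat(sprintf("<pairing_report> relationship: %s\n", x$relationship))
  cat("  switchback per-domain matches:",
      paste(x$per_domain_matches, collapse = " "),
      sprintf("(of %d)\n", x$layout$domain_length))
  cat(sprintf("  duplex matches: %d of %d\n",
              x$duplex_matches, x$layout$core_length))
  invisible(x)
}

#' Is a strand its own switchback complement?
#'
#' A strand whose every half-turn domain is a reverse-complement palindrome
#' equals its own switchback complement and therefore pairs with itself to
#' form a homodimeric switchback structure. By the same sequence design the
#' duplex complement of such a strand is again domain-palindromic, so it can
#' form a switchback homodimer of its own.
#'
#' @param seq a DNA sequence whose core partitions under `layout`.
#' @param layout a [domain_layout()].
#' @return a list with `self_complementary` (flag), `palindromic` (per-domain
#'   logical), `non_palindromic_domains` (indices), and `reason` (only set
#'   when the domain length is odd, which rules palindromes out entirely).
#' @examples
#' is_switchback_self_complementary("GGATCCGGTACC")$self_complementary  # TRUE
#' @export
is_switchback_self_complementary <- function(seq, layout = domain_layout()) {
  doms <- partition_domains(seq, layout)
  if (layout$domain_length %% 2L == 1L) {
    return(list(self_complementary = FALSE,
                palindromic = rep(FALSE, length(doms)),
                non_palindromic_domains = seq_along(doms),
                reason = paste0("odd domain length (",
                                layout$domain_length,
                                " nt): no reverse-complement palindrome exists")))
  }
  pal <- duplex_complement(doms) == doms
  list(self_complementary = all(pal),
       palindromic = pal,
       non_palindromic_domains = which(!pal),
       reason = NULL)
}

# deterministic pair-breaking transversion map
MUTATION_MAP <- c(A = "C", C = "A", G = "T", T = "G")

mutate_positions <- function(seq, layout, pos) {
  # pos: data.frame(domain, position) in core coordinates
  chars <- strsplit(layout_core(seq, layout), "")[[1]]
  idx <- (pos$domain - 1L) * layout$domain_length + pos$position
  chars[idx] <- MUTATION_MAP[chars[idx]]
  paste0(layout$cap5, paste(chars, collapse = ""), layout$cap3)
}

#' Mid-domain mismatch variants of a switchback strand
#'
#' Generates the canonical mismatch series used to probe domain-level
#' stability: an unmodified control, a single mismatch in one domain (1mm),
#' two adjacent mismatches in one domain (2mm-adj), and one mismatch in each
#' of two domains (2mm-sep). Mutations sit mid-domain — in-domain position
#' `ceiling(domain_length/2)` (and the next position for the adjacent pair) —
#' away from the strand-switch points, and use the fixed pair-breaking
#' transversion map A<->C, G<->T so the series is deterministic.
#'
#' @param seq a DNA sequence; core must partition under `layout`.
#' @param layout a [domain_layout()] with `domain_length >= 4`.
#' @return named list of `mismatch_design` objects (`control`, `1mm`,
#'   `2mm-adj`, `2mm-sep`), each with `variant_kind`, `mutated_positions`
#'   (data.frame domain/position) and `mutated_sequence`.
#' @examples
#' v <- make_mismatch_variants("CAGCAGCAGCAG")
#' v[["1mm"]]$mutated_positions
#' @export
make_mismatch_variants <- function(seq, layout = domain_layout()) {
  if (layout$domain_length < 4L)
    stop("domain_length must be >= 4 to define a mid-domain position",
         call. = FALSE)
  layout_core(seq, layout)  # validate
  mid <- as.integer(ceiling(layout$domain_length / 2))
  pos <- list(
    "control" = data.frame(domain = integer(), position = integer()),
    "1mm"     = data.frame(domain = 1L, position = mid),
    "2mm-adj" = data.frame(domain = c(1L, 1L), position = c(mid, mid + 1L)),
    "2mm-sep" = data.frame(domain = c(1L, 2L), position = c(mid, mid))
  )
  out <- lapply(names(pos), function(kind) {
    p <- pos[[kind]]
    structure(
      list(variant_kind = kind,
           mutated_positions = p,
           mutated_sequence = mutate_positions(seq, layout, p)),
      class = "mismatch_design"
    )
  })
  names(out) <- names(pos)
  out
}

#' @export
print.mismatch_design <- function(x, ...) {
  cat(sprintf("<mismatch_design> %s: %s (%d mutated position%s)\n",
              x$variant_kind, x$mutated_sequence,
              nrow(x$mutated_positions),
              if (nrow(x$mutated_positions) == 1L) "" else "s"))
  invisible(x)
}
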