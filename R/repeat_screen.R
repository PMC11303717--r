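#' Repeat motif constructor
#'
#' A short tandem repeat (STR) motif: a repeat unit of 1-12 nt, an optional
#' rotation phase, and a free-text annotation (e.g. the associated repeat
#' expansion disease).
#'
#' @param unit repeat unit sequence (1-12 nt).
#' @param phase rotation offset, 0 ... nchar(unit)-1; rotating the unit
#'   leaves the infinite tract unchanged up to a shift.
#' @param annotation optional label.
#' @return an object of class `repeat_motif`.
#' @examples
#' repeat_motif("CAG", annotation = "Huntington disease")
#' @export
repeat_motif <- function(unit, phase = 0L, annotation = NA_character_) {
  unit <- dna(unit)
  if (nchar(unit) > 12L)
    stop("repeat unit must be 1-12 nt", call. = FALSE)
  phase <- as.integer(phase)
  if (is.na(phase) || phase < 0L || phase >= nchar(unit))
    stop("phase must be in 0 ... ", nchar(unit) - 1L, call. = FALSE)
  structure(list(unit = unit, phase = phase, annotation = annotation),
            class = "repeat_motif")
}

# rotate a unit left by `phase` positions
rotate_unit <- function(unit, phase) {
  if (phase == 0L) return(unit)
  paste0(substr(unit, phase + 1L, nchar(unit)), substr(unit, 1L, phase))
}

# smallest period of the infinite tract tiled by `unit`
# (the minimal period of a periodic infinite word divides every period,
#  so it is the smallest divisor d of |unit| with unit = (unit[1..d])^k)
primitive_period <- function(unit) {
  L <- nchar(unit)
  for (d in seq_len(L)) {
    if (L %% d != 0L) next
    if (strrep(substr(unit, 1L, d), L %/% d) == unit) return(d)
  }
  L
}

#' Expand a repeat motif into a tract
#'
#' Tiles the (phase-rotated) unit and truncates to `total_length`.
#'
#' @param motif a [repeat_motif()], or a unit string (then `phase` applies).
#' @param total_length tract length in nt (>= unit length).
#' @param phase rotation offset used when `motif` is a bare string.
#' @return the tract sequence.
#' @examples
#' expand_repeat("CAG", 12)            # "CAGCAGCAGCAG"
#' expand_repeat("CAG", 6, phase = 1)  # "AGCAGC"
#' @export
expand_repeat <- function(motif, total_length, phase = 0L) {
  if (!inherits(motif, "repeat_motif")) motif <- repeat_motif(motif, phase)
  u <- rotate_unit(motif$unit, motif$phase)
  if (total_length < nchar(u))
    stop("total_length must be at least the unit length", call. = FALSE)
  substr(strrep(u, ceiling(total_length / nchar(u))), 1L, total_length)
}

#' Screen one repeat motif for switchback compatibility
#'
#' A repeat tract is switchback-compatible when its switchback complement
#' and its duplex complement are the same sequence, so that a single
#' partner strand can form either the conventional duplex or the switchback
#' structure. For a pure tract this holds exactly when the tract's smallest
#' period divides the half-turn domain length (6 bp by default) — which is
#' why trinucleotide disease repeats such as CAG/CTG qualify.
#'
#' @param motif a [repeat_motif()] or unit string.
#' @param layout a [domain_layout()]; the tract screened has the layout's
#'   core length.
#' @param phase rotation offset used when `motif` is a bare string.
#' @return a one-row data.frame: unit, phase, annotation, tract,
#'   switchback_complement_tract, duplex_complement_tract,
#'   switchback_compatible, reason.
#' @examples
#' is_switchback_compatible("CAG")$switchback_compatible   # TRUE
#' is_switchback_compatible("CCTG")$switchback_compatible  # FALSE
#' @export
is_switchback_compatible <- function(motif, layout = domain_layout(),
                                     phase = 0L) {
  if (!inherits(motif, "repeat_motif")) motif <- repeat_motif(motif, phase)
  bare <- domain_layout(layout$domain_length, layout$n_domains)
  tract <- expand_repeat(motif, bare$core_length)
  sb <- switchback_complement(tract, bare)
  du <- duplex_complement(tract)
  p <- primitive_period(motif$unit)
  compatible <- identical(sb, du)
  reason <- sprintf(
    "domain length %d %s a multiple of the tract's smallest period %d (unit %s)",
    layout$domain_length, if (layout$domain_length %% p == 0L) "is" else "is not",
    p, motif$unit)
  data.frame(unit = motif$unit, phase = motif$phase,
             annotation = motif$annotation, tract = tract,
             switchback_complement_tract = sb,
             duplex_complement_tract = du,
             switchback_compatible = compatible,
             reason = reason,
             stringsAsFactors = FALSE)
}

#' Screen a table of repeat motifs
#'
#' Runs [is_switchback_compatible()] over a motif table (TSV path or
#' data.frame with columns `unit`, and optionally `phase` and `annotation`).
#' Row order is preserved; per-row validation problems are collected in the
#' `error` column rather than aborting the screen.
#'
#' @param motifs TSV path or data.frame.
#' @param layout a [domain_layout()].
#' @return data.frame of screen records, one per motif row.
#' @examples
#' screen_motif_table(data.frame(unit = c("CAG", "CCTG")))
#' @export
screen_motif_table <- function(motifs, layout = domain_layout()) {
  if (is.character(motifs) && length(motifs) == 1L)
    motifs <- utils::read.delim(motifs, stringsAsFactors = FALSE,
                                comment.char = "#")
  if (nrow(motifs) == 0L) {
    out <- is_switchback_compatible("CAG", layout)[0, ]
    out$error <- character(0)
    return(out)
  }
  if (is.null(motifs$phase)) motifs$phase <- 0L
  if (is.null(motifs$annotation)) motifs$annotation <- NA_character_
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    tryCatch({
      r <- is_switchback_compatible(
        repeat_motif(motifs$unit[i], motifs$phase[i], motifs$annotation[i]),
        layout)
      r$error <- NA_character_
      r
    }, error = function(e) {
      data.frame(unit = as.character(motifs$unit[i]),
                 phase = suppressWarnings(as.integer(motifs$phase[i])),
                 annotation = motifs$annotation[i],
                 tract = NA_character_,
                 switchback_complement_tract = NA_character_,
                 duplex_complement_tract = NA_character_,
                 switchback_compatible = NA, reason = NA_character_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

# candidates from the self-offset criterion for one unit length:
# runs of seq[i] == seq[i + u] of length >= (min_copies - 1) * u
str_candidates <- function(chars, u, min_copies) {
  n <- length(chars)
  if (n < u * min_copies) return(NULL)
  eq <- chars[seq_len(n - u)] == chars[seq_len(n - u) + u]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= (min_copies - 1L) * u
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep],                  # 1-based
             end = ends[keep] + u,                  # 1-based inclusive
             unit_length = u)
}

#' Scan sequence for short tandem repeat loci
#'
#' Detects maximal tandem tracts by the self-offset criterion (runs of
#' `seq[i] == seq[i + u]`), reports each locus with its smallest repeat
#' period, and annotates switchback compatibility of the repeat unit under
#' the layout. Overlapping candidates are resolved by keeping the longer
#' tract, ties broken in favour of the smaller unit, so a pure (CAG)n tract
#' is reported once with unit CAG. Exact tandem tracts are strand-symmetric
#' (the reverse complement of a tandem tract is a tandem tract of the
#' complementary unit over the same interval), so the forward scan already
#' locates every locus; `strand = "both"` additionally scans the reverse
#' complement and drops reverse loci that coincide with a forward locus.
#'
#' @param x FASTA path, or a named character vector of contig sequences.
#' @param layout a [domain_layout()] used for the compatibility annotation.
#' @param min_copies minimum repeat copies (>= 2).
#' @param unit_lengths integer vector of unit lengths to scan.
#' @param strand `"forward"` (default) or `"both"`.
#' @return data.frame of loci: contig, start (0-based), end (half-open),
#'   unit, copies (possibly fractional), strand, switchback_compatible.
#' @examples
#' scan_sequence_for_strs(c(chr = paste0(strrep("A", 20),
#'                                       strrep("CAG", 8),
#'                                       strrep("A", 20))),
#'                        min_copies = 5)
#' @export
scan_sequence_for_strs <- function(x, layout = domain_layout(),
                                   min_copies = 5L, unit_lengths = 1:6,
                                   strand = c("forward", "both")) {
  strand <- match.arg(strand)
  if (is.character(x) && is.null(names(x)) && length(x) == 1L &&
      file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    x <- as.character(ss)
    names(x) <- sub("\\s.*", "", names(ss))
  }
  min_copies <- as.integer(min_copies)
  if (min_copies < 2L) stop("min_copies must be >= 2", call. = FALSE)

  scan_one <- function(seqstr, contig, strand_label) {
    chars <- strsplit(toupper(seqstr), "")[[1]]
    cands <- do.call(rbind, lapply(sort(unique(as.integer(unit_lengths))),
                                   function(u) str_candidates(chars, u, min_copies)))
    if (is.null(cands) || nrow(cands) == 0L) return(NULL)
    cands$len <- cands$end - cands$start + 1L
    # longer tract wins; ties to smaller unit (lowest-period reporting)
    cands <- cands[order(-cands$len, cands$unit_length, cands$start), ]
    taken <- logical(length(chars))
    keep <- logical(nrow(cands))
    for (i in seq_len(nrow(cands))) {
      span <- cands$start[i]:cands$end[i]
      if (!any(taken[span])) {
        keep[i] <- TRUE
        taken[span] <- TRUE
      }
    }
    cands <- cands[keep, , drop = FALSE]
    if (nrow(cands) == 0L) return(NULL)
    unit <- substr(rep(seqstr, nrow(cands)), cands$start,
                   cands$start + cands$unit_length - 1L)
    compatible <- vapply(unit, function(u)
      is_switchback_compatible(u, layout)$switchback_compatible, logical(1))
    data.frame(contig = contig,
               start = cands$start - 1L,             # 0-based half-open
               end = cands$end,
               unit = unit,
               copies = cands$len / cands$unit_length,
               strand = strand_label,
               switchback_compatible = unname(compatible),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  out <- list()
  for (contig in names(x)) {
    fwd <- scan_one(x[[contig]], contig, "+")
    out[[length(out) + 1L]] <- fwd
    if (strand == "both") {
      n <- nchar(x[[contig]])
      rev <- scan_one(duplex_complement(x[[contig]]), contig, "-")
      if (!is.null(rev)) {
        # map reverse-scan coordinates back to the forward strand
        s <- n - rev$end
        rev$end <- n - rev$start
        rev$start <- s
        if (!is.null(fwd)) {
          dup <- paste(rev$start, rev$end) %in% paste(fwd$start, fwd$end)
          rev <- rev[!dup, , drop = FALSE]
        }
        out[[length(out) + 1L]] <- rev
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), unit = character(),
                      copies = numeric(), strand = character(),
                      switchback_compatible = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}
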