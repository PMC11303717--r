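#' Read and write FASTA
#'
#' Thin wrappers over Biostrings that use plain named character vectors as
#' the in-memory representation. Writing normalizes line wrapping to a
#' fixed width; a write/read round-trip preserves identifiers, order and
#' sequence. Reading an empty file returns an empty vector with a warning;
#' a file whose first record lacks a `>` header is a malformed-record
#' error reporting the line number.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (!length(content)) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  first <- content[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA record at line ", first,
         ": expected a '>' header", call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width (nt).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write STR loci to BED6
#'
#' BED is 0-based half-open. The name column is `unit:copies:compatibility`,
#' the score column carries the copy number scaled by 10 and capped at
#' 1000, and rows are sorted by contig then start.
#'
#' @param loci data.frame from [scan_sequence_for_strs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  if (nrow(loci)) {
    if (any(loci$end <= loci$start))
      stop("BED intervals must satisfy end > start", call. = FALSE)
    loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
    bed <- data.frame(
      chrom = loci$contig,
      chromStart = loci$start,
      chromEnd = loci$end,
      name = sprintf("%s:%g:%s", loci$unit, loci$copies,
                     ifelse(loci$switchback_compatible, "compatible",
                            "incompatible")),
      score = pmin(1000L, as.integer(round(10 * loci$copies))),
      strand = loci$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Write STR loci to a 1-based TSV sidecar
#'
#' Human-readable companion to [write_bed()]: 1-based inclusive
#' coordinates (stated in the header comment), unit, copies and
#' compatibility.
#'
#' @param loci data.frame from [scan_sequence_for_strs()].
#' @param path output path.
#' @export
write_str_tsv <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  out <- data.frame(contig = loci$contig, start = loci$start + 1L,
                    end = loci$end, unit = loci$unit, copies = loci$copies,
                    strand = loci$strand,
                    switchback_compatible = loci$switchback_compatible)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1))
}

# reverse-complement-palindromic 6-mer: first half free, second half forced
random_palindromic_domain <- function(domain_length = 6L) {
  half <- paste(sample(c("A", "C", "G", "T"), domain_length %/% 2L,
                       replace = TRUE), collapse = "")
  paste0(half, duplex_complement(half))
}

random_gc_core <- function(length, gc_fraction) {
  n_gc <- round(gc_fraction * length)
  if (n_gc < 0 || n_gc > length)
    stop("GC target impossible at this length", call. = FALSE)
  base <- character(length)
  gc_pos <- sample(seq_len(length), n_gc)
  at_pos <- setdiff(seq_len(length), gc_pos)
  base[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  base[at_pos] <- sample(c("A", "T"), length(at_pos), replace = TRUE)
  paste(base, collapse = "")
}

#' Generate seeded fixtures for every module
#'
#' Produces the synthetic inputs the toolkit is exercised with, all
#' deterministic in the seed: random sequences; homodimer cores built from
#' random reverse-complement-palindromic 6-mers (strand-A analogues, each
#' verified switchback self-complementary); heterodimer cores at a target
#' GC content (67% by default, matching the GC content of typical
#' interacting-region designs); a synthetic genome with planted STR
#' tracts; Boltzmann melt curves with configured Tm/width/noise; the toy
#' NN table; and an example strand pool. Every artifact is validated by
#' the module that consumes it before being returned.
#'
#' @param seed integer seed (mandatory).
#' @param config list overriding any of: `n_random`, `random_length`,
#'   `n_homodimer_cores`, `n_heterodimer_cores`, `gc_fraction`,
#'   `core_length`, `genome_length`, `planted` (data.frame unit/copies/at),
#'   `melt` (list Tm_C/width/noise/T_range), `pool_total_M`.
#' @return a `fixture_bundle` list.
#' @examples
#' fx <- generate_fixtures(7)
#' fx$homodimer_cores
#' @export
generate_fixtures <- function(seed, config = list()) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- utils::modifyList(list(
    n_random = 10L, random_length = 24L,
    n_homodimer_cores = 4L, n_heterodimer_cores = 4L,
    gc_fraction = 2 / 3, core_length = 12L,
    genome_length = 10000L,
    planted = data.frame(unit = c("CAG", "CCTG"),
                         copies = c(20L, 15L),
                         at = c(1000L, 5000L),
                         stringsAsFactors = FALSE),
    melt = list(Tm_C = 55, width = 2, noise = 0.01,
                T_range = seq(15, 90, by = 0.5)),
    pool_total_M = 10e-6
  ), config)

  with_seed(seed, {
    layout <- domain_layout()

    random_sequences <- random_dna(cfg$n_random, cfg$random_length)

    homodimer_cores <- vapply(seq_len(cfg$n_homodimer_cores), function(i) {
      # strand-A analogue: switchback self-complementary, but with a
      # distinct duplex complement (redraw full palindromes, for which
      # "strand B" would be the same sequence as the core)
      repeat {
        core <- paste(vapply(seq_len(layout$n_domains), function(d)
          random_palindromic_domain(layout$domain_length), character(1)),
          collapse = "")
        if (!identical(core, duplex_complement(core))) return(core)
      }
    }, character(1))
    stopifnot(vapply(homodimer_cores, function(s)
      is_switchback_self_complementary(s, layout)$self_complementary,
      logical(1)))

    heterodimer_cores <- vapply(seq_len(cfg$n_heterodimer_cores), function(i)
      random_gc_core(cfg$core_length, cfg$gc_fraction), character(1))

    genome <- random_dna(1L, cfg$genome_length)
    for (k in seq_len(nrow(cfg$planted))) {
      tract <- strrep(cfg$planted$unit[k], cfg$planted$copies[k])
      at <- cfg$planted$at[k]
      substr(genome, at, at + nchar(tract) - 1L) <- tract
    }
    genome <- stats::setNames(genome, "synthetic_contig")

    melt_curve <- data.frame(
      temperature = cfg$melt$T_range,
      absorbance = 0.1 + 0.8 /
        (1 + exp((cfg$melt$Tm_C - cfg$melt$T_range) / cfg$melt$width)) +
        stats::rnorm(length(cfg$melt$T_range), sd = cfg$melt$noise))

    pool_core <- homodimer_cores[1]
    pool <- strand_pool(
      c(A = pool_core, B = duplex_complement(pool_core)),
      c(A = cfg$pool_total_M / 2, B = cfg$pool_total_M / 2), layout)

    structure(list(seed = seed, config = cfg,
                   random_sequences = random_sequences,
                   homodimer_cores = homodimer_cores,
                   heterodimer_cores = heterodimer_cores,
                   genome = genome,
                   melt_curve = melt_curve,
                   toy_nn_table = toy_nn_table(),
                   pool = pool),
              class = "fixture_bundle")
  })
}
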