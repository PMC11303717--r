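#' Construct specification
#'
#' A complete strand set for an experimental construct: named strands,
#' terminal labels (fluorophore/quencher identity and 5'/3' placement),
#' linkers, the intended pairings with their relationships, and free-text
#' design notes. Intended pairings are re-validated with [classify_pair()]
#' on construction.
#'
#' @param strands named character vector of sequences.
#' @param labels data.frame with columns strand, end ("5p"/"3p"), label;
#'   labels sit only on termini.
#' @param pairings data.frame with columns strand1, strand2, relationship,
#'   and optionally cap5/cap3/domain columns describing the layout the
#'   pairing is validated under.
#' @param layout a [domain_layout()] used to validate pairings (per-pairing
#'   caps override the layout's caps).
#' @param linkers named character vector of linker sequences used.
#' @param notes character vector of design notes.
#' @param validate re-check pairings (default TRUE).
#' @return an object of class `construct_spec`.
#' @export
construct_spec <- function(strands, labels = NULL, pairings = NULL,
                           layout = domain_layout(), linkers = character(),
                           notes = character(), validate = TRUE) {
  if (length(strands) < 1L || is.null(names(strands)))
    stop("construct needs at least one named strand", call. = FALSE)
  strands <- vapply(strands, dna, character(1))
  if (is.null(labels))
    labels <- data.frame(strand = character(), end = character(),
                         label = character(), stringsAsFactors = FALSE)
  stopifnot(all(labels$end %in% c("5p", "3p")),
            all(labels$strand %in% names(strands)))
  if (is.null(pairings))
    pairings <- data.frame(strand1 = character(), strand2 = character(),
                           relationship = character(),
                           stringsAsFactors = FALSE)
  if (validate && nrow(pairings)) {
    for (k in seq_len(nrow(pairings))) {
      rel <- classify_pair(strands[[pairings$strand1[k]]],
                           strands[[pairings$strand2[k]]], layout)$relationship
      want <- pairings$relationship[k]
      ok <- rel == want || (rel == "both" && want %in% c("duplex", "switchback"))
      if (!ok)
        stop("intended pairing ", pairings$strand1[k], "-",
             pairings$strand2[k], " classifies as '", rel,
             "', not '", want, "'", call. = FALSE)
    }
  }
  structure(list(strands = strands, labels = labels, pairings = pairings,
                 layout = layout, linkers = linkers, notes = notes),
            class = "construct_spec")
}

#' @export
print.construct_spec <- function(x, ...) {
  cat("<construct_spec>", length(x$strands), "strand(s)\n")
  for (nm in names(x$strands)) {
    lab <- x$labels[x$labels$strand == nm, ]
    lt <- if (nrow(lab))
      paste0("  [", paste(lab$end, lab$label, collapse = "; "), "]") else ""
    cat(sprintf("  %s: %s%s\n", nm, x$strands[[nm]], lt))
  }
  if (nrow(x$pairings)) {
    cat("intended pairings:\n")
    print(x$pairings, row.names = FALSE)
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = " | "), "\n")
  invisible(x)
}

#' Design a switchback strand set
#'
#' From a core sequence, generates the canonical three-strand set: X (the
#' core with caps), Y (its switchback complement) and Z (its duplex
#' complement), with the intended pairings XY = switchback and XZ = duplex
#' validated, and the core's GC content reported. Emits a homodimer
#' warning when the core is switchback self-complementary (strand-A-style
#' designs pair with themselves), and a note when Y and Z coincide (repeat
#' cores whose switchback and duplex complements are the same sequence).
#'
#' @param core the core sequence (no caps); must partition under the bare
#'   layout.
#' @param layout a [domain_layout()]; its cap fields are applied to all
#'   three strands (terminal thymines prevent aggregation).
#' @return a `construct_spec` with strands X, Y, Z.
#' @examples
#' design_switchback_set("AAAAAACCCCCC")
#' @export
design_switchback_set <- function(core, layout = domain_layout(cap5 = "T",
                                                               cap3 = "T")) {
  bare <- domain_layout(layout$domain_length, layout$n_domains)
  core <- dna(core)
  partition_domains(core, bare)
  y_core <- switchback_complement(core, bare)
  z_core <- duplex_complement(core)
  wrap <- function(s) paste0(layout$cap5, s, layout$cap3)
  strands <- c(X = wrap(core), Y = wrap(y_core), Z = wrap(z_core))
  gc <- mean(strsplit(core, "")[[1]] %in% c("G", "C"))
  notes <- sprintf("core GC content %.0f%%", 100 * gc)
  if (is_switchback_self_complementary(core, bare)$self_complementary) {
    warning("core is switchback self-complementary: X pairs with itself ",
            "(homodimer design)", call. = FALSE)
    notes <- c(notes, "homodimer design: X self-pairs in the switchback sense")
  }
  if (identical(y_core, z_core))
    notes <- c(notes,
               "switchback and duplex complements coincide (Y == Z)")
  construct_spec(strands,
                 pairings = data.frame(strand1 = c("X", "X"),
                                       strand2 = c("Y", "Z"),
                                       relationship = c("switchback", "duplex"),
                                       stringsAsFactors = FALSE),
                 layout = layout, notes = notes)
}

# synthetic DX scaffold segments (8 nt each): stand-ins chosen to avoid
# CAG/CTG-like content and >=6 nt complementary runs against the repeat
# regions used in the reporter
dx_scaffold_segments_synthetic <- function() {
  c(a = "ATACCTTC", b = "TCCTAACC", c = "ACTCATCC", d = "TACCTCTA")
}

#' Build a DX-scaffold reporter construct (synthetic scaffold)
#'
#' A double-crossover (DX) tile holds two single-stranded "interacting
#' regions" next to each other in parallel orientation, imposing the
#' geometric constraint that lets them form a switchback even though free
#' strands would prefer the conventional duplex. Two helices are each
#' covered by one continuous strand (S1, S2) and two crossover strands
#' (S3, S4) that exchange helices at the two crossover points; region 1 is
#' appended 5'->3' off helix 1 and region 2 off helix 2, each behind a
#' flexible linker (TT by default). Region 1 carries the quencher
#' (Iowa Black) on its 3' end and region 2 the fluorophore (fluorescein) on
#' its 3' end, so switchback formation between the regions quenches the
#' signal. The scaffold sequences are synthetic stand-ins with a validated
#' sequence-level crossover topology.
#'
#' The predicted interaction class is computed per half-turn domain with
#' the index-matched register (a domain interacts only on perfect
#' complementarity): `full` (all domains pair, e.g. (CTG)4 against (CAG)4),
#' `one-domain` (e.g. (CTG)2T6), or `none` (e.g. T12).
#'
#' @param region1 interacting region 1 (default (CAG)4).
#' @param region2 interacting region 2.
#' @param linker linker between scaffold and regions (default "TT").
#' @param layout a [domain_layout()] for the regions.
#' @param crosstalk_threshold regions pairing with scaffold strands at or
#'   above this contiguous complementarity are an error.
#' @return a `construct_spec` with strands S1...S4 and a
#'   `predicted_interaction` note.
#' @examples
#' build_dx_reporter(region2 = strrep("CTG", 4))
#' @export
build_dx_reporter <- function(region1 = strrep("CAG", 4),
                              region2 = strrep("T", 12),
                              linker = "TT", layout = domain_layout(),
                              crosstalk_threshold = 6L) {
  region1 <- dna(region1); region2 <- dna(region2)
  if (nchar(region1) != layout$core_length ||
      nchar(region2) != layout$core_length)
    stop("interacting regions must span the layout core (",
         layout$core_length, " nt)", call. = FALSE)
  seg <- dx_scaffold_segments_synthetic()
  strands <- c(
    S1 = paste0(seg[["a"]], seg[["b"]], linker, region1),
    S2 = paste0(seg[["c"]], seg[["d"]], linker, region2),
    S3 = paste0(duplex_complement(seg[["b"]]), duplex_complement(seg[["c"]])),
    S4 = paste0(duplex_complement(seg[["d"]]), duplex_complement(seg[["a"]]))
  )
  # per-domain interaction, index-matched register, perfect matches only
  d1 <- partition_domains(region1, layout)
  d2 <- partition_domains(region2, layout)
  pairing <- duplex_complement(d1) == d2
  interaction <- if (all(pairing)) "full" else
    if (sum(pairing) == 1L) "one-domain" else "none"

  labels <- data.frame(strand = c("S1", "S2"), end = c("3p", "3p"),
                       label = c("Iowa Black", "fluorescein"),
                       stringsAsFactors = FALSE)
  pairings <- data.frame(
    strand1 = c("S1", "S1", "S2", "S2",
                if (interaction != "none") "S1"),
    strand2 = c("S3", "S4", "S3", "S4",
                if (interaction != "none") "S2"),
    relationship = c(rep("scaffold", 4),
                     if (interaction != "none") "switchback"),
    stringsAsFactors = FALSE)
  spec <- construct_spec(
    strands, labels = labels, pairings = pairings, layout = layout,
    linkers = c(region = linker),
    notes = c("synthetic DX scaffold stand-in (segment topology a-b/c-d, crossovers S3: b'-c', S4: d'-a')",
              paste0("predicted_interaction: ", interaction)),
    validate = FALSE)
  # regions must not pair with any scaffold segment, top or bottom strand
  scaffold <- c(paste0(seg[["a"]], seg[["b"]]), paste0(seg[["c"]], seg[["d"]]),
                strands[["S3"]], strands[["S4"]])
  for (reg in c(region1, region2)) {
    runs <- vapply(scaffold, function(s)
      longest_complementary_run(reg, s, sense = "duplex"), integer(1))
    if (any(runs >= crosstalk_threshold))
      stop("interacting region pairs with a scaffold strand over ",
           max(runs), " nt (threshold ", crosstalk_threshold, ")",
           call. = FALSE)
  }
  spec
}

#' Predicted interaction class of a reporter spec
#'
#' @param spec a `construct_spec` from [build_dx_reporter()].
#' @return `"full"`, `"one-domain"` or `"none"`.
#' @export
predicted_interaction <- function(spec) {
  note <- grep("^predicted_interaction: ", spec$notes, value = TRUE)
  if (!length(note)) stop("spec has no predicted interaction note",
                          call. = FALSE)
  sub("^predicted_interaction: ", "", note[1])
}

# longest contiguous complementary run between two strands.
# duplex sense: antiparallel pairing at any alignment = longest common
# substring of s1 and the reverse complement of s2.
# switchback sense: strands parallel, pairing index-aligned within a run =
# longest common substring of s1 and the (unreversed) complement of s2.
longest_complementary_run <- function(s1, s2,
                                      sense = c("duplex", "switchback")) {
  sense <- match.arg(sense)
  t2 <- if (sense == "duplex") duplex_complement(s2)
        else chartr("ACGT", "TGCA", dna(s2))
  a <- strsplit(dna(s1), "")[[1]]
  b <- strsplit(t2, "")[[1]]
  best <- 0L
  prev <- integer(length(b))
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    match_j <- which(b == a[i])
    if (length(match_j)) {
      cur[match_j] <- 1L
      gt1 <- match_j[match_j > 1L]
      cur[gt1] <- prev[gt1 - 1L] + 1L
      best <- max(best, max(cur))
    }
    prev <- cur
  }
  as.integer(best)
}

#' Crosstalk check over a strand set
#'
#' Computes, for every strand pair including self-pairs, the maximal
#' contiguous complementarity in the duplex (antiparallel) and switchback
#' (parallel) senses, and flags pairs at or above the threshold that are
#' not intended pairings. One full half-turn domain (6 nt) is the default
#' threshold: anything shorter cannot nucleate a stable domain.
#'
#' @param spec a `construct_spec`.
#' @param threshold flag runs >= this length (nt).
#' @return a `crosstalk_report`: data.frame of pairs with run lengths and
#'   a `flagged` column.
#' @export
crosstalk_check <- function(spec, threshold = 6L) {
  nm <- names(spec$strands)
  intended <- character(0)
  if (nrow(spec$pairings))
    intended <- paste(pmin(spec$pairings$strand1, spec$pairings$strand2),
                      pmax(spec$pairings$strand1, spec$pairings$strand2))
  rows <- list()
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      dup <- longest_complementary_run(spec$strands[[i]], spec$strands[[j]],
                                       "duplex")
      sb <- longest_complementary_run(spec$strands[[i]], spec$strands[[j]],
                                      "switchback")
      key <- paste(min(nm[i], nm[j]), max(nm[i], nm[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        strand1 = nm[i], strand2 = nm[j],
        duplex_run = dup, switchback_run = sb,
        intended = key %in% intended,
        flagged = max(dup, sb) >= threshold && !(key %in% intended),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(list(pairs = out, threshold = threshold),
            class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat("<crosstalk_report> threshold", x$threshold, "nt\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Export / import a synthesis order sheet
#'
#' `export_order_sheet()` writes a FASTA of bare sequences plus a CSV in
#' synthesis-vendor style (name, sequence, 5' and 3' modification columns)
#' and a small metadata TSV (pairings, linkers, layout, notes) so that
#' `import_order_sheet()` on the output directory reproduces the spec.
#'
#' @param spec a `construct_spec` with at least one strand.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_order_sheet <- function(spec, dir) {
  if (length(spec$strands) == 0L)
    stop("cannot export an empty construct", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(spec$strands, file.path(dir, "strands.fasta"))
  lab5 <- stats::setNames(rep("", length(spec$strands)), names(spec$strands))
  lab3 <- lab5
  for (k in seq_len(nrow(spec$labels))) {
    tgt <- if (spec$labels$end[k] == "5p") "lab5" else "lab3"
    cur <- get(tgt)
    cur[spec$labels$strand[k]] <- spec$labels$label[k]
    assign(tgt, cur)
  }
  utils::write.csv(
    data.frame(name = names(spec$strands),
               sequence = unname(spec$strands),
               five_prime_mod = unname(lab5),
               three_prime_mod = unname(lab3),
               stringsAsFactors = FALSE),
    file.path(dir, "order_sheet.csv"), row.names = FALSE)
  utils::write.table(spec$pairings, file.path(dir, "pairings.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- c(
    paste0("domain_length\t", spec$layout$domain_length),
    paste0("n_domains\t", spec$layout$n_domains),
    paste0("cap5\t", spec$layout$cap5),
    paste0("cap3\t", spec$layout$cap3),
    paste0("linker\t", names(spec$linkers), "\t", unname(spec$linkers)),
    paste0("note\t", spec$notes))
  writeLines(meta, file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' @rdname export_order_sheet
#' @export
import_order_sheet <- function(dir) {
  strands <- read_fasta(file.path(dir, "strands.fasta"))
  sheet <- utils::read.csv(file.path(dir, "order_sheet.csv"),
                           stringsAsFactors = FALSE)
  sheet[is.na(sheet)] <- ""
  labels <- rbind(
    data.frame(strand = sheet$name, end = "5p", label = sheet$five_prime_mod,
               stringsAsFactors = FALSE),
    data.frame(strand = sheet$name, end = "3p", label = sheet$three_prime_mod,
               stringsAsFactors = FALSE))
  labels <- labels[nzchar(labels$label), , drop = FALSE]
  rownames(labels) <- NULL
  pairings <- utils::read.delim(file.path(dir, "pairings.tsv"),
                                stringsAsFactors = FALSE,
                                colClasses = "character")
  meta <- strsplit(readLines(file.path(dir, "meta.tsv")), "\t")
  field <- function(key) {
    hits <- meta[vapply(meta, function(m) m[1] == key, logical(1))]
    lapply(hits, function(m) if (length(m) > 1L) m[-1] else "")
  }
  one <- function(key, default = "") {
    v <- field(key)
    if (length(v)) v[[1]][1] else default
  }
  layout <- domain_layout(as.integer(one("domain_length", "6")),
                          as.integer(one("n_domains", "2")),
                          cap5 = one("cap5"), cap3 = one("cap3"))
  linkers <- field("linker")
  linkers <- if (length(linkers))
    stats::setNames(vapply(linkers, `[`, character(1), 2),
                    vapply(linkers, `[`, character(1), 1))
  else character()
  notes <- vapply(field("note"), paste, character(1), collapse = "\t")
  construct_spec(strands, labels = labels, pairings = pairings,
                 layout = layout, linkers = linkers, notes = notes,
                 validate = FALSE)
}
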