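# gas constant, kcal / (mol K)
R_KCAL <- 1.987e-3
# gas constant, cal / (mol K), for Tm from dH (kcal) / dS (cal)
R_CAL <- 1.987

#' Nearest-neighbor parameter tables
#'
#' An NN table holds per-dinucleotide-stack enthalpies (kcal/mol) and
#' entropies (cal/(mol K)), duplex initiation terms keyed by terminal base
#' class (G/C vs A/T), a symmetry correction for self-complementary
#' duplexes, and an entropic salt-correction coefficient per phosphate.
#' `default_nn_table()` loads the standard unified DNA parameter set
#' shipped with the package (provenance label `unified-1998`, 1 M NaCl
#' reference state); `read_nn_table()`/`write_nn_table()` round-trip a
#' table through its TSV serialization.
#'
#' @param path TSV path (columns kind/key/dH/dS; `#` comments allowed, a
#'   `# provenance:` line is honoured).
#' @return an object of class `nn_table`.
#' @examples
#' tab <- default_nn_table()
#' tab$stacks["CG", ]
#' @export
read_nn_table <- function(path) {
  first <- readLines(path, n = 1L)
  provenance <- if (startsWith(first, "# provenance:"))
    trimws(sub("# provenance:", "", first)) else NA_character_
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stacks <- df[df$kind == "stack", ]
  if (nrow(stacks) != 16L || anyDuplicated(stacks$key))
    stop("NN table must contain exactly the 16 dinucleotide stacks",
         call. = FALSE)
  init <- df[df$kind == "init", ]
  sym <- df[df$kind == "symmetry", ]
  salt <- df[df$kind == "salt", ]
  structure(
    list(stacks = data.frame(dH = stacks$dH, dS = stacks$dS,
                             row.names = stacks$key),
         init = data.frame(dH = init$dH, dS = init$dS, row.names = init$key),
         symmetry = if (nrow(sym)) c(dH = sym$dH[1], dS = sym$dS[1])
                    else c(dH = 0, dS = 0),
         salt_per_phosphate = if (nrow(salt)) salt$dS[1] else 0,
         provenance = provenance),
    class = "nn_table"
  )
}

#' @rdname read_nn_table
#' @export
default_nn_table <- function() {
  read_nn_table(system.file("extdata", "nn_unified.tsv",
                            package = "switchbackdna", mustWork = TRUE))
}

#' @rdname read_nn_table
#' @param table an `nn_table`.
#' @export
write_nn_table <- function(table, path) {
  rows <- rbind(
    data.frame(kind = "stack", key = rownames(table$stacks),
               dH = table$stacks$dH, dS = table$stacks$dS),
    data.frame(kind = "init", key = rownames(table$init),
               dH = table$init$dH, dS = table$init$dS),
    data.frame(kind = "symmetry", key = "symmetry",
               dH = table$symmetry[["dH"]], dS = table$symmetry[["dS"]]),
    data.frame(kind = "salt", key = "per_phosphate",
               dH = 0, dS = table$salt_per_phosphate)
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(table$provenance))
    writeLines(paste0("# provenance: ", table$provenance), con)
  utils::write.table(format(rows, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Toy nearest-neighbor table
#'
#' A didactic table in which every stack contributes exactly -1 kcal/mol to
#' the free energy at any temperature (dH = -1, dS = 0), with zero
#' initiation, symmetry and salt terms. Free energies then reduce to stack
#' counting, which makes the junction (eliminated-stack) arithmetic easy to
#' inspect.
#'
#' @return an `nn_table`.
#' @export
toy_nn_table <- function() {
  keys <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG",
            "TT", "TG", "AC", "AG", "TC", "CC")
  structure(
    list(stacks = data.frame(dH = rep(-1, 16), dS = rep(0, 16),
                             row.names = keys),
         init = data.frame(dH = c(0, 0), dS = c(0, 0),
                           row.names = c("GC", "AT")),
         symmetry = c(dH = 0, dS = 0),
         salt_per_phosphate = 0,
         provenance = "toy"),
    class = "nn_table"
  )
}

#' Experimental condition for thermodynamic predictions
#'
#' Temperatures are degrees Celsius at the interface and kelvin internally.
#' Defaults mirror a typical switchback assembly buffer: 8 uM total strand
#' concentration in TAE with 12.5 mM magnesium acetate. Switchback DNA
#' requires at least 10 mM Mg2+ to be stable; predictions for switchback
#' structures below that threshold are flagged unreliable rather than
#' corrected, since only the threshold is known.
#'
#' @param temperature_C condition temperature, degrees C.
#' @param total_strand_M total strand concentration C_T (M).
#' @param monovalent_M monovalent cation concentration (M).
#' @param mg_mM Mg2+ concentration (mM).
#' @return an object of class `thermo_condition`.
#' @export
thermo_condition <- function(temperature_C = 25, total_strand_M = 8e-6,
                             monovalent_M = 0.05, mg_mM = 12.5) {
  if (temperature_C <= -273.15) stop("temperature below absolute zero",
                                     call. = FALSE)
  if (total_strand_M < 0 || monovalent_M < 0 || mg_mM < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  structure(list(temperature_C = temperature_C,
                 temperature_K = temperature_C + 273.15,
                 total_strand_M = total_strand_M,
                 monovalent_M = monovalent_M, mg_mM = mg_mM),
            class = "thermo_condition")
}

# effective monovalent concentration (M); divalent-aware empirical
# equivalence Na_eq = Na + 120 sqrt(Mg), concentrations in mM
effective_monovalent <- function(cond) {
  (cond$monovalent_M * 1000 + 120 * sqrt(cond$mg_mM)) / 1000
}

# dinucleotide stacks of a sequence, 5'->3'
stacks_of <- function(seq) {
  substring(seq, seq_len(nchar(seq) - 1L), 2:nchar(seq))
}

lookup_stacks <- function(stacks, table) {
  missing <- setdiff(unique(stacks), rownames(table$stacks))
  if (length(missing))
    stop("missing stack parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  table$stacks[stacks, , drop = FALSE]
}

init_terms <- function(seq, table) {
  cls <- function(b) if (b %in% c("G", "C")) "GC" else "AT"
  ends <- c(cls(substr(seq, 1L, 1L)), cls(substr(seq, nchar(seq), nchar(seq))))
  colSums(table$init[ends, , drop = FALSE])
}

make_thermo_result <- function(dH, dS, cond, kind, junctions, symmetric,
                               reliable = TRUE) {
  TK <- cond$temperature_K
  dG <- dH - TK * dS / 1000
  Kd <- exp(dG / (R_KCAL * TK))
  ct_factor <- if (symmetric) 1 else 4
  Tm_C <- if (cond$total_strand_M > 0)
    dH * 1000 / (dS + R_CAL * log(cond$total_strand_M / ct_factor)) - 273.15
  else NA_real_
  structure(list(dH = dH, dS = dS, dG = dG, Tm_C = Tm_C, Kd = Kd,
                 kind = kind, junctions = junctions,
                 symmetric = symmetric, reliable = reliable,
                 condition = cond),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "<thermo_result> %s: dH %.2f kcal/mol, dS %.2f cal/(mol K),\n  dG(%.1f C) %.2f kcal/mol, Tm %.1f C, Kd %.3g M (%d junction%s)%s\n",
    x$kind, x$dH, x$dS, x$condition$temperature_C, x$dG, x$Tm_C, x$Kd,
    x$junctions, if (x$junctions == 1L) "" else "s",
    if (!x$reliable) " [below Mg threshold: unreliable]" else ""))
  invisible(x)
}

#' Nearest-neighbor thermodynamics of a conventional duplex
#'
#' Two-state prediction for a sequence paired with its full duplex
#' (reverse) complement: dH and dS are the sum over the L-1 dinucleotide
#' stacks plus the terminal initiation terms, dS is salt-corrected per
#' phosphate to the condition's effective monovalent concentration, and Tm
#' follows the two-state formula with total strand concentration C_T
#' (symmetry factor 1 for self-complementary sequences, 4 otherwise).
#'
#' @param seq a DNA sequence, length >= 2.
#' @param table an `nn_table` (default: the shipped unified set).
#' @param cond a [thermo_condition()].
#' @return a `thermo_result` with dH (kcal/mol), dS (cal/(mol K)),
#'   dG at the condition temperature (kcal/mol), Tm (C) and Kd (M).
#' @examples
#' nn_duplex_thermo("CAGCAGCAGCAG")
#' @export
nn_duplex_thermo <- function(seq, table = default_nn_table(),
                             cond = thermo_condition()) {
  seq <- dna(seq)
  if (nchar(seq) < 2L)
    stop("sequence must be at least 2 nt for a stack model", call. = FALSE)
  st <- lookup_stacks(stacks_of(seq), table)
  ini <- init_terms(seq, table)
  symmetric <- identical(seq, duplex_complement(seq))
  dH <- sum(st$dH) + ini[["dH"]]
  dS <- sum(st$dS) + ini[["dS"]] +
    (if (symmetric) table$symmetry[["dS"]] else 0)
  dS <- dS + table$salt_per_phosphate * (nchar(seq) - 1L) *
    log(effective_monovalent(cond))
  make_thermo_result(dH, dS, cond, "duplex", 0L, symmetric)
}

# dH/dS of the inter-domain (junction) stacks eliminated in the switchback
junction_stacks <- function(core, layout, table) {
  b <- seq_len(layout$n_domains - 1L) * layout$domain_length
  lookup_stacks(substring(core, b, b + 1L), table)
}

#' Nearest-neighbor thermodynamics of a switchback structure
#'
#' Starts from the duplex prediction for the layout core and removes the
#' contribution of each inter-domain stack: at every strand-switch point the
#' continuous base pairing is interrupted and one base stack of the
#' equivalent duplex is eliminated (n_domains - 1 junctions). On top of the
#' lost stacking, a per-junction free-energy penalty accounts for the
#' junction itself; by default it is booked as purely entropic (dH is
#' reduced only by the lost stacks, matching the observation that the
#' switchback's enthalpy deficit comes from stacking while its entropic
#' penalty is smaller than the duplex's), switchable to enthalpic
#' bookkeeping.
#'
#' Because eliminated stacks are stabilizing (negative dG) and the penalty
#' is non-negative, the switchback is never predicted more stable than its
#' conventional duplex counterpart.
#'
#' @param seq a DNA sequence whose core partitions under `layout`.
#' @param layout a [domain_layout()].
#' @param table an `nn_table`.
#' @param penalty per-junction free-energy penalty, kcal/mol (default:
#'   [default_junction_penalty()] for the given table/condition).
#' @param cond a [thermo_condition()]; if `mg_mM` is below the 10 mM
#'   stability threshold the result is flagged unreliable.
#' @param bookkeeping how the penalty is split: `"entropic"` (default)
#'   leaves dH untouched, `"enthalpic"` adds it to dH.
#' @return a `thermo_result` with `kind = "switchback"` and the junction
#'   count recorded.
#' @examples
#' switchback_thermo("CAGCAGCAGCAG", penalty = 0.5)
#' @export
switchback_thermo <- function(seq, layout = domain_layout(),
                              table = default_nn_table(), penalty = NULL,
                              cond = thermo_condition(),
                              bookkeeping = c("entropic", "enthalpic")) {
  bookkeeping <- match.arg(bookkeeping)
  core <- layout_core(seq, layout)
  if (is.null(penalty)) penalty <- default_junction_penalty(table, cond)
  base <- nn_duplex_thermo(core, table, cond)
  jn <- junction_stacks(core, layout, table)
  n_j <- layout$n_domains - 1L
  TK <- cond$temperature_K
  dH <- base$dH - sum(jn$dH)
  dS <- base$dS - sum(jn$dS)
  if (bookkeeping == "entropic") {
    dS <- dS - penalty * 1000 * n_j / TK
  } else {
    dH <- dH + penalty * n_j
  }
  # switchback homodimer symmetry: the strand is its own switchback partner
  symmetric <- is_switchback_self_complementary(seq, layout)$self_complementary
  make_thermo_result(dH, dS, cond, "switchback", n_j, symmetric,
                     reliable = cond$mg_mM >= 10)
}

#' Calibrate the per-junction penalty from observed free energies
#'
#' Given measured free energies of a duplex and its switchback counterpart
#' at a common temperature, returns the per-junction penalty that makes the
#' model's free-energy gap equal the observed gap. The observed total
#' junction cost is `dG_switchback_obs - dG_duplex_obs`; the penalty is
#' that cost per junction plus the (negative) free energy of the eliminated
#' junction stacks, so the calibrated model reproduces the observed gap by
#' construction.
#'
#' @param dG_duplex_obs,dG_switchback_obs observed free energies (kcal/mol)
#'   at the condition temperature.
#' @param seq sequence used to look up the eliminated junction stacks.
#' @param layout a [domain_layout()].
#' @param table an `nn_table`.
#' @param cond a [thermo_condition()].
#' @return list with `penalty` (kcal/mol per junction), `junction_cost`
#'   (total observed dG gap, kcal/mol), `eliminated_stack_dG` (kcal/mol,
#'   summed over junctions) and `n_junctions`.
#' @examples
#' calibrate_junction_penalty(-12.23, -10.26, "CAGCAGCAGCAG")
#' @export
calibrate_junction_penalty <- function(dG_duplex_obs, dG_switchback_obs,
                                       seq, layout = domain_layout(),
                                       table = default_nn_table(),
                                       cond = thermo_condition()) {
  n_j <- layout$n_domains - 1L
  if (n_j < 1L) stop("layout has no junctions", call. = FALSE)
  core <- layout_core(seq, layout)
  jn <- junction_stacks(core, layout, table)
  TK <- cond$temperature_K
  elim_dG <- sum(jn$dH - TK * jn$dS / 1000)
  cost <- dG_switchback_obs - dG_duplex_obs
  list(penalty = (cost + elim_dG) / n_j,
       junction_cost = cost,
       eliminated_stack_dG = elim_dG,
       n_junctions = n_j)
}

#' Default per-junction penalty
#'
#' Shipped calibration from the measured free-energy pair of a two-domain
#' heterodimer switchback and its conventional duplex (-12.23 and -10.26
#' kcal/mol at 25 C, a total junction cost of 1.97 kcal/mol). The identity
#' of the eliminated stack in that construct is not published, so its free
#' energy is taken as the mean stack free energy of the table at the
#' condition temperature; recalibration for a known sequence is one
#' [calibrate_junction_penalty()] call.
#'
#' @param table an `nn_table`.
#' @param cond a [thermo_condition()].
#' @return penalty in kcal/mol per junction.
#' @export
default_junction_penalty <- function(table = default_nn_table(),
                                     cond = thermo_condition()) {
  TK <- cond$temperature_K
  mean_stack_dG <- mean(table$stacks$dH - TK * table$stacks$dS / 1000)
  (-10.26 - (-12.23)) + mean_stack_dG
}

#' Convert between free energy and dissociation constant
#'
#' `dG = R T ln(Kd / 1 M)` with R = 1.987e-3 kcal/(mol K). A Kd below 1 M
#' therefore maps to a negative (favourable) free energy of association.
#'
#' @param value Kd in M (for `"kd_to_dG"`) or dG in kcal/mol
#'   (for `"dG_to_kd"`).
#' @param direction conversion direction.
#' @param temperature_C temperature in degrees C (default 25).
#' @return the converted value.
#' @examples
#' free_energy_kd_convert(30.7e-9, "kd_to_dG")  # about -10.25 kcal/mol
#' @export
free_energy_kd_convert <- function(value,
                                   direction = c("kd_to_dG", "dG_to_kd"),
                                   temperature_C = 25) {
  direction <- match.arg(direction)
  TK <- temperature_C + 273.15
  if (direction == "kd_to_dG") {
    if (any(value <= 0)) stop("Kd must be positive", call. = FALSE)
    R_KCAL * TK * log(value)
  } else {
    exp(value / (R_KCAL * TK))
  }
}

#' Complex concentration from nucleotide concentration
#'
#' Assay amounts are often quoted in nucleotide concentration so they
#' transfer between structures of different sizes; the molar concentration
#' of the assembled complex is the nucleotide concentration divided by the
#' number of nucleotides per complex (e.g. 80 uM nucleotides at 28 nt per
#' two-strand complex is 2.86 uM complex).
#'
#' @param nucleotide_M nucleotide concentration (M).
#' @param nt_per_complex total nucleotides per assembled complex.
#' @return complex concentration (M).
#' @examples
#' complex_concentration(80e-6, 28)  # 2.857e-06
#' @export
complex_concentration <- function(nucleotide_M, nt_per_complex) {
  if (any(nt_per_complex <= 0)) stop("nt_per_complex must be positive",
                                     call. = FALSE)
  nucleotide_M / nt_per_complex
}

#' Fit a melt curve to the Boltzmann sigmoid
#'
#' Least-squares fit of the four-parameter Boltzmann function
#' `A(T) = lower + (upper - lower) / (1 + exp((Tm - T) / width))`
#' to a normalized UV melting curve; Tm is the inflection, where the fitted
#' curve equals the baseline midpoint. Points outside `fit_range` are
#' dropped before fitting (melt transitions for switchback structures are
#' typically fit over 15-65 C, conventional duplexes over 15-90 C).
#'
#' @param curve data.frame or two-column table: temperature (C) and
#'   normalized absorbance.
#' @param fit_range numeric length-2 temperature window, C.
#' @return a `boltzmann_fit`: `Tm_C`, `width`, `lower`, `upper`,
#'   `residual_norm`, `converged`, and the fitted model object. A flat or
#'   unfittable curve returns `converged = FALSE` with diagnostics instead
#'   of an error.
#' @examples
#' tc <- seq(20, 80, by = 1)
#' ab <- 0.1 + 0.8 / (1 + exp((55 - tc) / 2))
#' fit_melt_curve(data.frame(tc, ab))$Tm_C
#' @export
fit_melt_curve <- function(curve, fit_range = c(15, 65)) {
  if (is.character(curve) && length(curve) == 1L)
    curve <- utils::read.delim(curve, stringsAsFactors = FALSE)
  tt <- curve[[1]]
  aa <- curve[[2]]
  keep <- tt >= fit_range[1] & tt <= fit_range[2]
  tt <- tt[keep]; aa <- aa[keep]
  fail <- function(msg) structure(
    list(Tm_C = NA_real_, width = NA_real_, lower = NA_real_,
         upper = NA_real_, residual_norm = NA_real_, converged = FALSE,
         diagnostics = msg, fit = NULL),
    class = "boltzmann_fit")
  if (length(tt) < 8L) return(fail("fewer than 8 points in fit range"))
  if (diff(range(aa)) < 1e-6) return(fail("flat curve: no transition"))
  start <- list(lower = min(aa), upper = max(aa),
                Tm = tt[which.min(abs(aa - (min(aa) + max(aa)) / 2))],
                width = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      aa ~ lower + (upper - lower) / (1 + exp((Tm - tt) / width)),
      start = start, control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear least squares did not converge"))
  cf <- stats::coef(fit)
  # a width collapsing to ~0 or a Tm outside the data is a failed transition
  converged <- is.finite(cf[["Tm"]]) && abs(cf[["width"]]) > 1e-8 &&
    cf[["Tm"]] >= min(tt) - 10 && cf[["Tm"]] <= max(tt) + 10
  structure(
    list(Tm_C = unname(cf[["Tm"]]), width = unname(cf[["width"]]),
         lower = unname(cf[["lower"]]), upper = unname(cf[["upper"]]),
         residual_norm = sqrt(sum(stats::residuals(fit)^2)),
         converged = converged, diagnostics = NULL, fit = fit),
    class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<boltzmann_fit> Tm %.2f C, width %.2f, baselines %.3f / %.3f, |r| %.3g\n",
      x$Tm_C, x$width, x$lower, x$upper, x$residual_norm))
  else
    cat("<boltzmann_fit> not converged:", x$diagnostics, "\n")
  invisible(x)
}

#' Coarse mismatch thermodynamics at domain level
#'
#' Applies the domain-level stability rule to a mismatch variant: in the
#' switchback structure a domain carrying two or more internal mismatches
#' counts as melted (its stacks and a proportional share of any junction
#' bookkeeping are removed), while a single mismatch costs a fixed
#' free-energy increment. The rule reproduces the observed stability order
#' control > 1mm > 2mm-sep > 2mm-adj: adjacent mismatches sacrifice an
#' entire half-turn domain, separated ones only pay twice the single
#' increment. For the conventional duplex the structure has no domain
#' substructure and each mismatch costs the fixed increment.
#'
#' @param seq the unmutated reference sequence.
#' @param design a `mismatch_design` from [make_mismatch_variants()].
#' @param layout a [domain_layout()].
#' @param structure `"switchback"` or `"duplex"`.
#' @param table,penalty,cond,bookkeeping as in [switchback_thermo()].
#' @param increment free-energy cost per isolated mismatch, kcal/mol.
#' @return a `thermo_result`.
#' @export
mismatch_thermo <- function(seq, design, layout = domain_layout(),
                            structure = c("switchback", "duplex"),
                            table = default_nn_table(), penalty = NULL,
                            cond = thermo_condition(), increment = 1.5,
                            bookkeeping = "entropic") {
  structure_kind <- match.arg(structure)
  pos <- design$mutated_positions
  TK <- cond$temperature_K
  if (structure_kind == "duplex") {
    base <- nn_duplex_thermo(layout_core(seq, layout), table, cond)
    dS <- base$dS - nrow(pos) * increment * 1000 / TK
    return(make_thermo_result(base$dH, dS, cond, "duplex", 0L,
                              base$symmetric))
  }
  base <- switchback_thermo(seq, layout, table, penalty, cond,
                            bookkeeping = bookkeeping)
  core <- layout_core(seq, layout)
  doms <- partition_domains(seq, layout)
  counts <- tabulate(pos$domain, nbins = layout$n_domains)
  dH <- base$dH; dS <- base$dS
  for (d in seq_len(layout$n_domains)) {
    if (counts[d] >= 2L) {
      # melted domain: remove its internal stacks and terminal-equivalent share
      st <- lookup_stacks(stacks_of(doms[d]), table)
      dH <- dH - sum(st$dH)
      dS <- dS - sum(st$dS)
    } else if (counts[d] == 1L) {
      dS <- dS - increment * 1000 / TK
    }
  }
  make_thermo_result(dH, dS, cond, "switchback", base$junctions,
                     FALSE, reliable = base$reliable)
}
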