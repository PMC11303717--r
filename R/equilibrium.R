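#' Strand pool
#'
#' A named set of strands with total concentrations (M) and the pairing
#' layout under which their relationships are classified.
#'
#' @param strands named character vector of sequences.
#' @param concentrations named numeric vector of totals (M); names must
#'   match `strands`.
#' @param layout a [domain_layout()].
#' @return an object of class `strand_pool`.
#' @examples
#' strand_pool(c(A = "GGATCCGGTACC", B = "GGTACCGGATCC"),
#'             c(A = 5e-6, B = 2e-6))
#' @export
strand_pool <- function(strands, concentrations, layout = domain_layout()) {
  if (is.null(names(strands)) || anyDuplicated(names(strands)))
    stop("strands must have unique names", call. = FALSE)
  strands <- vapply(strands, dna, character(1))
  if (!setequal(names(concentrations), names(strands)))
    stop("concentration names must match strand names", call. = FALSE)
  concentrations <- concentrations[names(strands)]
  if (any(concentrations < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  for (s in strands) layout_core(s, layout)  # validate
  structure(list(strands = strands, concentrations = concentrations,
                 layout = layout),
            class = "strand_pool")
}

#' Enumerate feasible dimeric species in a pool
#'
#' Every ordered-agnostic strand pair (including self-pairs) whose
#' classification is duplex, switchback or both defines a feasible dimer.
#' Species carry their relationship tag; a "both" pair (one partner strand
#' serving either geometry, as for CAG/CTG repeats) is tagged `both`.
#'
#' @param pool a [strand_pool()].
#' @return data.frame: species, strand1, strand2, relationship, homo.
#' @examples
#' p <- strand_pool(c(A = "GGATCCGGTACC", B = "GGTACCGGATCC"),
#'                  c(A = 1e-6, B = 1e-6))
#' enumerate_species(p)
#' @export
enumerate_species <- function(pool) {
  # canonical (sorted) strand order: species sets, names and downstream
  # partitions are then independent of the order strands were added in
  nm <- sort(names(pool$strands))
  out <- list()
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      rel <- classify_pair(pool$strands[[nm[i]]], pool$strands[[nm[j]]],
                           pool$layout)$relationship
      if (rel != "none")
        out[[length(out) + 1L]] <- data.frame(
          species = paste0(nm[i], nm[j]),
          strand1 = nm[i], strand2 = nm[j],
          relationship = rel, homo = i == j,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(species = character(), strand1 = character(),
                      strand2 = character(), relationship = character(),
                      homo = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

make_partition <- function(pool, species, conc, free, model, diagnostics) {
  species$concentration <- unname(conc)
  structure(list(species = species, free = free, model = model,
                 totals = pool$concentrations,
                 diagnostics = diagnostics),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("<species_partition> model: %s\n", x$model))
  if (nrow(x$species))
    print(x$species[, c("species", "relationship", "concentration")],
          row.names = FALSE)
  cat("free monomers (M):\n")
  print(x$free)
  invisible(x)
}

#' Per-strand mass-conservation check
#'
#' Bound strands are counted per complex: 2x for homodimers, 1x per strand
#' for heterodimers. Returns the maximum relative residual
#' |free + bound - total| / total over strands with nonzero totals.
#'
#' @param partition a `species_partition`.
#' @return maximum relative residual (numeric scalar).
#' @export
mass_balance_residual <- function(partition) {
  tot <- partition$totals
  res <- 0
  for (s in names(tot)) {
    if (tot[[s]] == 0) next
    bound <- 0
    sp <- partition$species
    for (k in seq_len(nrow(sp))) {
      mult <- (sp$strand1[k] == s) + (sp$strand2[k] == s)
      bound <- bound + mult * sp$concentration[k]
    }
    res <- max(res, abs(partition$free[[s]] + bound - tot[[s]]) / tot[[s]])
  }
  res
}

#' Partition a pool under the absolute-preference rule
#'
#' The limit model of structural preference observed in strand-competition
#' gels: strands pair into conventional duplexes first (duplexes fill at
#' the minimum of the available partners; a strand facing several duplex
#' partners splits proportionally to their availability), remaining
#' strands pair into heterodimeric switchbacks, then strands capable of
#' switchback self-pairing homodimerize completely, and anything left
#' stays free. "Both"-tagged species count as duplexes (the duplex is the
#' preferred geometry).
#'
#' @param pool a [strand_pool()].
#' @return a `species_partition` with `model = "absolute"`.
#' @examples
#' p <- strand_pool(c(A = "GGATCCGGTACC", B = "GGTACCGGATCC"),
#'                  c(A = 5e-6, B = 2e-6))
#' absolute_preference_partition(p)
#' @export
absolute_preference_partition <- function(pool) {
  sp <- enumerate_species(pool)
  conc <- numeric(nrow(sp))
  rem <- pool$concentrations[sort(names(pool$concentrations))]
  eps <- 1e-15 * max(sum(rem), 1e-300)

  fill_tier <- function(idx) {
    # proportional allocation rounds; exact in one round when no strand
    # has competing partners in the tier
    for (round in 1:200) {
      active <- idx[vapply(idx, function(k) {
        if (sp$homo[k]) rem[[sp$strand1[k]]] > eps
        else rem[[sp$strand1[k]]] > eps && rem[[sp$strand2[k]]] > eps
      }, logical(1))]
      if (!length(active)) break
      # each strand offers its remainder split proportional to partner supply
      offer <- matrix(0, nrow = length(active), ncol = 2)
      for (a in seq_along(active)) {
        k <- active[a]
        for (side in 1:2) {
          s <- sp[[paste0("strand", side)]][k]
          partner <- sp[[paste0("strand", 3 - side)]][k]
          others <- active[vapply(active, function(m)
            sp$strand1[m] == s || sp$strand2[m] == s, logical(1))]
          supply <- vapply(others, function(m) {
            p <- if (sp$strand1[m] == s) sp$strand2[m] else sp$strand1[m]
            rem[[p]]
          }, numeric(1))
          w <- rem[[partner]] / sum(supply)
          offer[a, side] <- rem[[s]] * w
        }
      }
      moved <- 0
      for (a in seq_along(active)) {
        k <- active[a]
        f <- if (sp$homo[k]) offer[a, 1] / 2 else min(offer[a, ])
        if (f <= 0) next
        conc[k] <<- conc[k] + f
        if (sp$homo[k]) {
          rem[[sp$strand1[k]]] <<- max(0, rem[[sp$strand1[k]]] - 2 * f)
        } else {
          rem[[sp$strand1[k]]] <<- max(0, rem[[sp$strand1[k]]] - f)
          rem[[sp$strand2[k]]] <<- max(0, rem[[sp$strand2[k]]] - f)
        }
        moved <- max(moved, f)
      }
      if (moved <= eps) break
    }
  }

  if (nrow(sp)) {
    fill_tier(which(sp$relationship %in% c("duplex", "both")))
    fill_tier(which(sp$relationship == "switchback" & !sp$homo))
    fill_tier(which(sp$relationship == "switchback" & sp$homo))
  }
  make_partition(pool, sp, conc, rem, "absolute",
                 list(note = "tiered allocation: duplex > hetero switchback > homo switchback"))
}

# association constants (M^-1) from the NN model; hetero species carry the
# statistical factor 2 relative to homodimers so that equal per-contact
# energetics reproduce 1:2:1 random-pairing statistics
default_association_constants <- function(pool, species,
                                          table = default_nn_table(),
                                          penalty = NULL,
                                          cond = thermo_condition()) {
  vapply(seq_len(nrow(species)), function(k) {
    s1 <- pool$strands[[species$strand1[k]]]
    rel <- species$relationship[k]
    th <- if (rel %in% c("duplex", "both"))
      nn_duplex_thermo(layout_core(s1, pool$layout), table, cond)
    else
      switchback_thermo(s1, pool$layout, table, penalty, cond)
    ka <- exp(-th$dG / (R_KCAL * cond$temperature_K))
    if (species$homo[k]) ka else 2 * ka
  }, numeric(1))
}

#' Partition a pool by mass action
#'
#' Solves the coupled dimerization equilibria `[SiSj] = Kij [Si][Sj]`
#' (`[SiSi] = Kii [Si]^2`) under per-strand mass conservation by damped
#' Newton iteration on the free-monomer concentrations: full Newton steps,
#' halved (factor 0.5) whenever an iterate would go negative or fail to
#' reduce the residual, deterministic initialization at free = total / 2,
#' 200-iteration cap. Convergence is declared at a relative
#' mass-conservation residual below 1e-12.
#'
#' @param pool a [strand_pool()].
#' @param association_constants named numeric vector (M^-1) by species
#'   name; default derives them from the nearest-neighbor model, giving
#'   hetero species the statistical factor 2 over homodimers.
#' @param ... passed to the default-constant derivation (`table`,
#'   `penalty`, `cond`).
#' @return a `species_partition` with `model = "mass_action"` and solver
#'   diagnostics (iterations, residual, converged).
#' @examples
#' p <- strand_pool(c(A = "GGATCCGGTACC", B = "GGTACCGGATCC"),
#'                  c(A = 1e-6, B = 1e-6))
#' mass_action_partition(p, c(AA = 1e6, AB = 1e12, BB = 1e6))
#' @export
mass_action_partition <- function(pool, association_constants = NULL, ...) {
  sp <- enumerate_species(pool)
  nm <- sort(names(pool$strands))
  tot <- unname(pool$concentrations[nm])
  n <- length(nm)

  if (nrow(sp) == 0L || all(tot == 0)) {
    free <- pool$concentrations[nm]
    return(make_partition(pool, sp, numeric(nrow(sp)), free, "mass_action",
                          list(iterations = 0L, residual = 0, converged = TRUE)))
  }
  if (is.null(association_constants)) {
    K <- default_association_constants(pool, sp, ...)
  } else {
    if (!all(sp$species %in% names(association_constants)))
      stop("association_constants must name every feasible species: ",
           paste(sp$species, collapse = ", "), call. = FALSE)
    K <- unname(association_constants[sp$species])
  }
  if (any(K < 0)) stop("association constants must be >= 0", call. = FALSE)

  i1 <- match(sp$strand1, nm)
  i2 <- match(sp$strand2, nm)

  complexes <- function(f) K * f[i1] * f[i2]
  residual_vec <- function(f) {
    cc <- complexes(f)
    bound <- numeric(n)
    for (k in seq_along(cc)) {
      bound[i1[k]] <- bound[i1[k]] + cc[k]
      bound[i2[k]] <- bound[i2[k]] + cc[k]
    }
    f + bound - tot
  }
  scale <- ifelse(tot > 0, tot, max(tot))
  relres <- function(g) max(abs(g) / scale)

  f <- tot / 2
  g <- residual_vec(f)
  iter <- 0L
  while (iter < 200L && relres(g) > 1e-12) {
    iter <- iter + 1L
    J <- diag(1, n)
    for (k in seq_along(K)) {
      a <- i1[k]; b <- i2[k]
      if (a == b) {
        J[a, a] <- J[a, a] + 4 * K[k] * f[a]
      } else {
        J[a, a] <- J[a, a] + K[k] * f[b]
        J[b, b] <- J[b, b] + K[k] * f[a]
        J[a, b] <- J[a, b] + K[k] * f[a]
        J[b, a] <- J[b, a] + K[k] * f[b]
      }
    }
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      f_new <- f + lambda * step
      if (all(f_new >= 0)) {
        g_new <- residual_vec(f_new)
        if (relres(g_new) < relres(g) || lambda < 1e-12) break
      }
      lambda <- lambda * 0.5
      if (lambda < 1e-14) { f_new <- f; g_new <- g; break }
    }
    if (identical(f_new, f)) break
    f <- f_new
    g <- g_new
  }
  conc <- complexes(f)
  free <- stats::setNames(f, nm)
  make_partition(pool, sp, conc, free, "mass_action",
                 list(iterations = iter, residual = relres(g),
                      converged = relres(g) <= 1e-12))
}

#' Titration / displacement series over a concentration grid
#'
#' Computes one equilibrium partition per row of a concentration grid.
#' Both models are path-independent, so the endpoint of a displacement
#' experiment (duplex complement added to a pre-assembled switchback)
#' equals the co-annealed partition at the same totals: an invading duplex
#' complement converts the switchback without any single-stranded toehold,
#' driven purely by structural preference.
#'
#' @param strands named character vector of sequences.
#' @param conc_grid numeric matrix (points x strands, columns named like
#'   `strands`) of total concentrations (M).
#' @param layout a [domain_layout()].
#' @param model `"absolute"` or `"mass_action"`.
#' @param ... passed to the partition function (e.g.
#'   `association_constants`).
#' @return list with `partitions` (one `species_partition` per row) and
#'   `summary` (data.frame: one row per grid point with per-species and
#'   per-free-strand concentrations).
#' @examples
#' grid <- ratio_grid(0:10, 10:0, c("A", "B"), total = 10e-6)
#' titration_series(c(A = "GGATCCGGTACC", B = "GGTACCGGATCC"), grid)
#' @export
titration_series <- function(strands, conc_grid, layout = domain_layout(),
                             model = c("absolute", "mass_action"), ...) {
  model <- match.arg(model)
  if (is.null(colnames(conc_grid)) ||
      !setequal(colnames(conc_grid), names(strands)))
    stop("conc_grid columns must be named after the strands", call. = FALSE)
  parts <- vector("list", nrow(conc_grid))
  for (r in seq_len(nrow(conc_grid))) {
    pool <- strand_pool(strands, conc_grid[r, names(strands)], layout)
    parts[[r]] <- tryCatch(
      switch(model,
             absolute = absolute_preference_partition(pool),
             mass_action = mass_action_partition(pool, ...)),
      error = function(e) e)
  }
  ok <- !vapply(parts, inherits, logical(1), "condition")
  rows <- lapply(which(ok), function(r) {
    p <- parts[[r]]
    vals <- c(stats::setNames(as.list(conc_grid[r, names(strands)]),
                              paste0("total_", names(strands))),
              stats::setNames(as.list(p$species$concentration),
                              p$species$species),
              stats::setNames(as.list(unname(p$free)),
                              paste0("free_", names(p$free))))
    as.data.frame(vals)
  })
  list(partitions = parts,
       summary = if (length(rows)) do.call(rbind, rows) else data.frame())
}

#' Build a two-strand ratio grid
#'
#' Convenience constructor for competition grids like 10:0 ... 0:10 at a
#' fixed total strand concentration.
#'
#' @param parts1,parts2 numeric vectors of relative parts per point.
#' @param strand_names length-2 character vector of column names.
#' @param total total strand concentration (M) at each point; each point's
#'   parts are normalized by `max(parts1 + parts2)` so that, e.g., the
#'   5:5 point of a 10-part grid puts `total/2` in each strand.
#' @return numeric matrix usable as `conc_grid` in [titration_series()].
#' @export
ratio_grid <- function(parts1, parts2, strand_names, total = 10e-6) {
  denom <- max(parts1 + parts2)
  m <- cbind(parts1, parts2) / denom * total
  colnames(m) <- strand_names
  m
}
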