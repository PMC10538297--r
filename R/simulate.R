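#' Configuration for the stepwise-mutation Y-STR simulator
#'
#' The forward model: each haploid lineage descends independently from a
#' common founder haplotype for `generations` generations; per generation
#' each STR allele copy mutates with probability `mu`, stepping one repeat
#' up or down with equal probability (single-step symmetric stepwise
#' mutation, the model under which Rst is the natural differentiation
#' statistic). Y-InDel loci are drawn from fixed state frequencies;
#' microvariant lineages carry an inherited fractional offset (e.g. 14.1)
#' that mutates in whole-repeat steps. Multi-copy loci evolve one value per
#' copy and are reported as one unordered state; a small per-lineage rate
#' of an extra copy produces tri-allelic patterns.
#'
#' @param n Individuals per population.
#' @param panel A [panel_def()] (default: the 44-marker extended panel).
#' @param mu Per-locus per-generation mutation rate (default 3.35e-3, the
#'   average Y-STR rate).
#' @param generations Generations of drift from the founder.
#' @param founder Optional named list of founder repeat values; drawn
#'   uniformly from `founder_range` when `NULL`.
#' @param delta Mean repeat shift applied to population B's founder in
#'   [simulate_divergent_pair()].
#' @param seed Integer seed; identical configs give identical samples.
#' @param founder_range Integer range founder repeats are drawn from.
#' @param microvariant_loci STR loci eligible for fractional-offset
#'   lineages.
#' @param microvariant_freq Per-lineage probability of the +0.1 offset at
#'   an eligible locus.
#' @param indel_freq Frequency of the insertion state at InDel loci.
#' @param extra_copy_rate Per-lineage probability of an extra allele copy
#'   at a multi-copy locus (tri-allelic pattern).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n = 312L, panel = default_panels()$extended_44,
                       mu = 3.35e-3, generations = 200L, founder = NULL,
                       delta = 0, seed = 1L,
                       founder_range = c(10L, 25L),
                       microvariant_loci = c("DYS458", "DYS518", "DYS576",
                                             "DYS557"),
                       microvariant_freq = 0.02,
                       indel_freq = 0.5,
                       extra_copy_rate = 0.003) {
  stopifnot(n >= 1L, mu >= 0, mu <= 1, generations >= 0L, delta >= 0)
  structure(list(n = as.integer(n), panel = panel, mu = mu,
                 generations = as.integer(generations), founder = founder,
                 delta = delta, seed = as.integer(seed),
                 founder_range = founder_range,
                 microvariant_loci = microvariant_loci,
                 microvariant_freq = microvariant_freq,
                 indel_freq = indel_freq,
                 extra_copy_rate = extra_copy_rate),
            class = "sim_config")
}

# Evaluate expr under a seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Net repeat drift after g generations for length(k) lineages.
net_steps <- function(n_lineages, g, mu) {
  k <- stats::rbinom(n_lineages, g, mu)
  2L * stats::rbinom(n_lineages, k, 0.5) - k
}

format_repeat <- function(v) {
  frac <- round(v %% 1, 1)
  ifelse(frac == 0, sprintf("%d", as.integer(round(v))),
         sprintf("%.1f", v))
}

# Draw a founder haplotype: one repeat value per allele copy.
draw_founder <- function(panel, founder_range) {
  lo <- founder_range[1]; hi <- founder_range[2]
  founder <- list()
  for (l in panel$loci) {
    if (l %in% panel$indel_loci) next
    ncopy <- if (l %in% panel$multi_copy) 2L else 1L
    founder[[l]] <- sample(seq(lo, hi), ncopy, replace = TRUE)
  }
  founder
}

simulate_cells <- function(cfg, founder, prefix) {
  panel <- cfg$panel
  n <- cfg$n
  g <- cfg$generations
  cells <- matrix(NA_character_, n, length(panel$loci),
                  dimnames = list(NULL, panel$loci))
  for (l in panel$loci) {
    if (l %in% panel$indel_loci) {
      states <- sample(c("I", "D"), n, replace = TRUE,
                       prob = c(cfg$indel_freq, 1 - cfg$indel_freq))
      cells[, l] <- states
      next
    }
    base <- founder[[l]]
    ncopy <- length(base)
    vals <- matrix(rep(base, each = n), n, ncopy) +
      matrix(net_steps(n * ncopy, g, cfg$mu), n, ncopy)
    vals <- pmax(vals, 1L)
    if (l %in% cfg$microvariant_loci && !(l %in% panel$multi_copy)) {
      hit <- stats::runif(n) < cfg$microvariant_freq
      vals[hit, 1] <- vals[hit, 1] + 0.1
    }
    if (ncopy > 1L && cfg$extra_copy_rate > 0) {
      extra <- stats::runif(n) < cfg$extra_copy_rate
      third <- vals[, ncopy] + sample(c(-1L, 1L), n, replace = TRUE)
      cells[, l] <- vapply(seq_len(n), function(i) {
        v <- vals[i, ]
        if (extra[i]) v <- c(v, max(1, third[i]))
        paste(format_repeat(sort(v)), collapse = ",")
      }, "")
    } else {
      cells[, l] <- if (ncopy == 1L) format_repeat(vals[, 1]) else
        vapply(seq_len(n), function(i)
          paste(format_repeat(sort(vals[i, ])), collapse = ","), "")
    }
  }
  pop_sample(prefix, sprintf("%s_%04d", prefix, seq_len(n)), cells,
             panel = panel)
}

#' Simulate one population under the stepwise mutation model
#'
#' @param cfg A [sim_config()].
#' @param name Population name.
#' @return A [pop_sample()] with the founder haplotype attached as
#'   attribute `"founder"`; a pure function of the config (same seed, same
#'   table).
#' @export
simulate_population <- function(cfg, name = "sim") {
  with_seed(cfg$seed, {
    founder <- if (is.null(cfg$founder)) draw_founder(cfg$panel,
                                                      cfg$founder_range)
               else cfg$founder
    s <- simulate_cells(cfg, founder, name)
    attr(s, "founder") <- founder
    s
  })
}

#' Simulate a pair of populations at tunable divergence
#'
#' Both populations descend from a common founder; population B's founder
#' is shifted by `+delta` repeats at every STR allele copy before
#' within-population evolution, so `delta = 0` reduces to two independent
#' draws from one population and large `delta` (relative to the
#' within-population variance accumulated by drift) drives Rst towards 1.
#'
#' @param cfg A [sim_config()]; `cfg$delta` sets the shift.
#' @param names Length-2 character vector of population names.
#' @return List of two [pop_sample()] objects.
#' @export
simulate_divergent_pair <- function(cfg, names = c("popA", "popB")) {
  with_seed(cfg$seed, {
    founder <- if (is.null(cfg$founder)) draw_founder(cfg$panel,
                                                      cfg$founder_range)
               else cfg$founder
    shifted <- lapply(founder, function(v) v + cfg$delta)
    a <- simulate_cells(cfg, founder, names[1])
    b <- simulate_cells(cfg, shifted, names[2])
    list(a, b)
  })
}

#' Construct a sample realizing an exact haplotype frequency spectrum
#'
#' Builds a population whose haplotype spectrum has exactly the requested
#' multiplicities — e.g. `list(c(1, 296), c(2, 8))` yields 296 singleton
#' haplotypes plus 8 haplotypes seen twice (n = 312, 304 distinct). Distinct
#' states are guaranteed to differ at one or more single-copy STR loci via a
#' mixed-radix encoding over a per-locus allele alphabet; the alphabet
#' assignment and row order are shuffled under the seed.
#'
#' @param spectrum_spec List of `c(multiplicity, number_of_states)` pairs
#'   (or a 2-column matrix).
#' @param panel A [panel_def()] providing the locus space.
#' @param seed Integer seed.
#' @param founder_range Integer range for the allele alphabet.
#' @param name Population name.
#' @return A [pop_sample()] whose [haplotype_spectrum()] matches the
#'   request exactly.
#' @export
sample_from_spectrum <- function(spectrum_spec,
                                 panel = default_panels()$extended_44,
                                 seed = 1L,
                                 founder_range = c(10L, 25L),
                                 name = "synthetic") {
  spec <- do.call(rbind, lapply(spectrum_spec, function(x) {
    stopifnot(length(x) == 2L, x[1] >= 1, x[2] >= 1)
    c(mult = as.integer(x[1]), states = as.integer(x[2]))
  }))
  S <- sum(spec[, "states"])
  n <- sum(spec[, "mult"] * spec[, "states"])
  str_loci <- setdiff(panel$loci, panel$indel_loci)
  if (!length(str_loci)) {
    stop("panel has no STR loci to realize distinct states", call. = FALSE)
  }
  a <- founder_range[2] - founder_range[1] + 1L
  if (length(str_loci) * log(a) < log(S)) {
    stop(sprintf("infeasible spectrum: %d distinct states exceed the %d-locus state space",
                 S, length(str_loci)), call. = FALSE)
  }
  with_seed(seed, {
    # per-locus permuted alphabets keep digit -> allele a bijection
    alphabets <- lapply(str_loci, function(l)
      sample(seq(founder_range[1], founder_range[2])))
    names(alphabets) <- str_loci
    indel_states <- lapply(panel$indel_loci, function(l)
      sample(c("I", "D"), S, replace = TRUE))
    names(indel_states) <- panel$indel_loci

    cells_of_state <- function(s) {      # s is 0-based
      row <- stats::setNames(character(length(panel$loci)), panel$loci)
      rem <- s
      for (l in str_loci) {
        digit <- rem %% a
        rem <- rem %/% a
        v <- alphabets[[l]][digit + 1L]
        row[l] <- if (l %in% panel$multi_copy)
          paste(sort(c(v, v + 2L)), collapse = ",") else as.character(v)
      }
      for (l in panel$indel_loci) row[l] <- indel_states[[l]][s + 1L]
      row
    }
    states <- t(vapply(seq_len(S) - 1L, cells_of_state,
                       character(length(panel$loci))))
    mult <- rep(rep(spec[, "mult"], spec[, "states"]))
    rows <- states[rep(seq_len(S), mult), , drop = FALSE]
    rows <- rows[sample(nrow(rows)), , drop = FALSE]
    pop_sample(name, sprintf("%s_%04d", name, seq_len(n)), rows,
               panel = panel)
  })
}
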