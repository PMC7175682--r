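#' Integer transform of a weighted diet composition
#'
#' Rarefaction by subsampling without replacement operates on integer
#' abundances, so the percentage composition is first converted: each taxon's
#' percentage is multiplied by the number of loads in the sample to give a
#' whole-pollen-load equivalent (e.g. 40% of a 14-load sample is 5.6 loads),
#' then multiplied by ten and rounded to the nearest whole number
#' (half away from zero), giving counts in tenth-of-a-load units. Taxa that
#' round to zero are dropped.
#'
#' @param shares named numeric vector of percentages summing to 100 (+/-
#'   0.5), typically a `diet_profile`'s `species_level`.
#' @param n_loads number of loads behind the composition.
#' @param bee_species optional label carried through to the result.
#' @return A `pollen_counts` list: `bee_species`, `counts` (named integer
#'   vector, tenth-of-a-load units), `n_loads`, `total_units`.
#' @examples
#' integer_transform(c(A = 40, B = 60), n_loads = 14)$counts  # A 56, B 84
#' @export
integer_transform <- function(shares, n_loads, bee_species = NA_character_) {
  stopifnot(n_loads >= 1)
  if (abs(sum(shares) - 100) > 0.5) {
    stop("shares sum to ", format(sum(shares)), ", not 100 (+/- 0.5)")
  }
  units <- round_half_away(shares / 100 * n_loads * 10)
  units <- units[units > 0]
  structure(list(bee_species = bee_species,
                 counts = units, n_loads = as.integer(n_loads),
                 total_units = sum(units)),
            class = "pollen_counts")
}

# round half away from zero ("scientific" rounding), unlike base round()'s
# round-half-even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Expected rarefied richness (closed form)
#'
#' Hypergeometric expectation of the number of distinct taxa in a subsample
#' of `subsample_units` units drawn without replacement from the pooled
#' counts: E[S] = sum over taxa of (1 - C(N - N_t, n) / C(N, n)). Serves as
#' the analytic oracle for the Monte-Carlo procedure and as a fast exact
#' path.
#'
#' @param counts a `pollen_counts` object or a named non-negative integer
#'   vector.
#' @param subsample_units number of units to draw (<= total units).
#' @return Expected distinct-taxon count (real, >= 1 for any non-empty
#'   subsample).
#' @export
rarefy_exact <- function(counts, subsample_units) {
  n_t <- if (inherits(counts, "pollen_counts")) counts$counts else counts
  n_t <- n_t[n_t > 0]
  N <- sum(n_t)
  n <- subsample_units
  if (n > N) stop("subsample (", n, ") larger than total units (", N, ")")
  sum(1 - exp(lchoose(N - n_t, n) - lchoose(N, n)))
}

#' Rarefied diet breadth by resampling without replacement
#'
#' Draws `target_loads` x 10 units without replacement from the pooled
#' integer-transformed counts, `n_resamples` times, and reports the mean and
#' standard deviation of the number of distinct taxa per draw. The target is
#' expressed in loads to match how diet breadth is standardised across bee
#' species with unequal sample sizes.
#'
#' @param counts a `pollen_counts` object (see [integer_transform()]).
#' @param target_loads standardised sample size in loads (e.g. 12 or 3).
#' @param n_resamples number of random subsamples (default 1000).
#' @param seed integer seed making the resampling reproducible.
#' @return A `rarefied_breadth` list: `bee_species`, `target_loads`,
#'   `expected_richness`, `resample_sd`, `n_resamples`, `seed`.
#' @export
rarefy <- function(counts, target_loads, n_resamples = 1000, seed = 1L) {
  stopifnot(inherits(counts, "pollen_counts"), n_resamples >= 1)
  n <- target_loads * 10
  N <- counts$total_units
  if (n > N) {
    stop("subsample of ", target_loads, " loads (", n,
         " units) exceeds the ", N, " available units")
  }
  pool <- rep.int(seq_along(counts$counts), counts$counts)
  richness <- local_seed(seed, {
    vapply(seq_len(n_resamples),
           function(i) length(unique(pool[sample.int(N, n)])),
           numeric(1))
  })
  structure(list(bee_species = counts$bee_species,
                 target_loads = as.integer(target_loads),
                 expected_richness = mean(richness),
                 resample_sd = stats::sd(richness),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed)),
            class = "rarefied_breadth")
}

# evaluate expr under a given RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rarefy every qualifying profile to a standard number of loads
#'
#' Applies [integer_transform()] + [rarefy()] to each profile whose pooled
#' units suffice for the target (total units >= target x 10 — a species
#' never enters a rarefied comparison with less material than the target
#' subsample). Rarefaction runs over the finest taxon resolution the
#' profiles carry (distinct pollen types).
#'
#' @param profiles list of `diet_profile` objects.
#' @param target_loads standardised sample size in loads.
#' @param n_resamples,seed passed to [rarefy()] (each species' resampling is
#'   seeded with `seed` + its position, so a run is reproducible end to end).
#' @return data.frame with columns `bee_species`, `target_loads`,
#'   `expected_richness`, `resample_sd`, `n_resamples`, `seed`; species with
#'   too little material are omitted (listed in attribute `excluded`).
#' @export
rarefy_profiles <- function(profiles, target_loads, n_resamples = 1000,
                            seed = 1L) {
  rows <- list()
  excluded <- character(0)
  i <- 0L
  for (p in profiles) {
    i <- i + 1L
    shares <- if (!is.null(p$species_level)) p$species_level else
      p$family_level
    counts <- integer_transform(shares, p$n_loads, p$bee_species)
    if (counts$total_units < target_loads * 10) {
      excluded <- c(excluded, p$bee_species)
      next
    }
    r <- rarefy(counts, target_loads, n_resamples, seed + i)
    rows[[length(rows) + 1]] <- data.frame(
      bee_species = r$bee_species, target_loads = r$target_loads,
      expected_richness = r$expected_richness, resample_sd = r$resample_sd,
      n_resamples = r$n_resamples, seed = r$seed, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(bee_species = character(0), target_loads = integer(0),
               expected_richness = numeric(0), resample_sd = numeric(0),
               n_resamples = integer(0), seed = integer(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
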