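#' Simulate a pool of species centroid sequences
#'
#' Generates `n_species` equal-length marker sequences whose pairwise
#' Jukes-Cantor distances are all at least `min_between_jc`, by rejection
#' sampling: a uniform-random ACGT ancestor is drawn, and candidate
#' centroids are produced by per-site Jukes-Cantor substitutions of the
#' ancestor until each candidate clears the between-species floor against
#' every accepted centroid.  The default length (421 nt) is the marker
#' insert left by a 461-bp amplicon after removing two 20-nt primers.
#'
#' @param n_species Number of species centroids (>= 1).
#' @param length Sequence length in nt (>= 30, default 421).
#' @param min_between_jc Minimum pairwise Jukes-Cantor distance between
#'   centroids, in substitutions/site, in (0, 0.5] (default 0.08, twice the
#'   0.04 species cutoff so groups are unambiguous).
#' @param seed Integer RNG seed; the pool is fully determined by it.
#' @param max_tries Rejection-sampling attempts allowed per centroid before
#'   the combination is declared infeasible.
#' @return A tibble of class `species_pool` with columns `species_id` and
#'   `sequence`, and attribute `min_between_jc`.
#' @export
simulate_species_pool <- function(n_species, length = 421, min_between_jc = 0.08,
                                  seed, max_tries = 2000L) {
  stopifnot(n_species >= 1, length >= 30,
            min_between_jc > 0, min_between_jc <= 0.5)
  # per-site substitution probability targeting pairwise JC ~ 1.5x the floor,
  # capped below saturation; two sequences mutated independently at rate q
  # differ at a site with probability 2q - (4/3)q^2
  target_p <- min(0.7, 0.75 * (1 - exp(-4 * 1.5 * min_between_jc / 3)))
  q <- (2 - sqrt(4 - 16 * target_p / 3)) / (8 / 3)
  bases <- c("A", "C", "G", "T")
  local_seed(seed, {
    ancestor <- sample(bases, length, replace = TRUE)
    accepted <- list()
    while (base::length(accepted) < n_species) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- ancestor
        hit <- runif(length) < q
        if (any(hit)) {
          cand[hit] <- vapply(
            cand[hit], function(b) sample(setdiff(bases, b), 1L), ""
          )
        }
        cand_str <- paste(cand, collapse = "")
        clear <- all(vapply(accepted, function(a) {
          p <- sum(strsplit(a, "")[[1L]] != cand) / length
          p < 0.75 && jc_correction(p) >= min_between_jc
        }, logical(1)))
        if (clear) {
          accepted[[base::length(accepted) + 1L]] <- cand_str
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "infeasible species pool: could not place centroid %d of %d at JC >= %.3f with length %d after %d attempts",
          base::length(accepted) + 1L, n_species, min_between_jc, length, max_tries
        ))
      }
    }
    pool <- tibble(
      species_id = sprintf("sp%02d", seq_len(n_species)),
      sequence = unlist(accepted)
    )
    attr(pool, "min_between_jc") <- min_between_jc
    class(pool) <- c("species_pool", class(pool))
    pool
  })
}

#' Simulate ASV variants around each species centroid
#'
#' Each species contributes one or more ASVs obtained by substituting a
#' bounded number of sites of its centroid, so that every ASV is guaranteed
#' within `max_within_jc` (Jukes-Cantor) of its own centroid.  Requiring
#' `max_within_jc < min_between_jc / 2` makes species separable by the
#' triangle inequality on p-distances.  The first variant of every species
#' is the centroid itself.
#'
#' @param pool A `species_pool` from [simulate_species_pool()].
#' @param variants_per_species Either a single count applied to all species
#'   or a length-2 range `c(min, max)` sampled uniformly per species
#'   (default `c(1, 22)`, the observed range of ASVs per species-like
#'   group).
#' @param max_within_jc Maximum Jukes-Cantor distance of a variant from its
#'   centroid (default 0.02).
#' @param seed Integer RNG seed.
#' @return A tibble of class `asv_truth` with columns `asv_id`,
#'   `species_id`, `sequence`: the simulated ASVs and their ground-truth
#'   species map.
#' @export
simulate_asv_variants <- function(pool, variants_per_species = c(1, 22),
                                  max_within_jc = 0.02, seed) {
  stopifnot(inherits(pool, "species_pool"))
  min_between <- attr(pool, "min_between_jc")
  if (!(max_within_jc < min_between / 2)) {
    abort(sprintf(
      "separability requires max_within_jc (%.4f) < min_between_jc / 2 (%.4f)",
      max_within_jc, min_between / 2
    ))
  }
  L <- nchar(pool$sequence[[1L]])
  # largest site count m with jc(m / L) <= max_within_jc
  p_max <- 0.75 * (1 - exp(-4 * max_within_jc / 3))
  m_max <- floor(p_max * L + 1e-9)
  bases <- c("A", "C", "G", "T")
  local_seed(seed, {
    rows <- purrr::map2_dfr(pool$species_id, pool$sequence, function(sp, cen) {
      k <- if (length(variants_per_species) == 2L) {
        sample(variants_per_species[1L]:variants_per_species[2L], 1L)
      } else {
        as.integer(variants_per_species)
      }
      cen_chars <- strsplit(cen, "")[[1L]]
      seqs <- character(0)
      guard <- 0L
      while (length(seqs) < k) {
        guard <- guard + 1L
        if (guard > 200L * k) {
          abort(sprintf("could not draw %d distinct variants for %s", k, sp))
        }
        m <- if (length(seqs) == 0L) 0L else sample.int(m_max + 1L, 1L) - 1L
        v <- cen_chars
        if (m > 0L) {
          sites <- sample.int(L, m)
          v[sites] <- vapply(v[sites], function(b) sample(setdiff(bases, b), 1L), "")
        }
        vs <- paste(v, collapse = "")
        if (!vs %in% seqs) seqs <- c(seqs, vs)
      }
      tibble(species_id = sp, sequence = seqs)
    })
    dup <- duplicated(rows$sequence)
    if (any(dup)) rows <- rows[!dup, , drop = FALSE]  # cross-species collision: keep first
    rows <- mutate(rows, asv_id = sprintf("ASV%04d", dplyr::row_number()),
                   .before = 1L)
    class(rows) <- c("asv_truth", class(rows))
    attr(rows, "max_within_jc") <- max_within_jc
    rows
  })
}

#' Simulate per-site species abundances
#'
#' Species relative abundances at each site follow a geometric rank-abundance
#' series \eqn{a_i \propto \theta (1-\theta)^{i-1}} with a site-specific
#' random permutation of which species occupies which rank, so sites share a
#' rank-abundance shape but differ in composition.
#'
#' @param species_ids Character vector of species ids.
#' @param sites Character vector of site names (default four ISCS-like
#'   sites).
#' @param theta Geometric-series parameter in (0, 1) (default 0.3).
#' @param seed Integer RNG seed.
#' @return A tibble `site`, `species_id`, `abundance`; abundances sum to 1
#'   within each site.
#' @export
simulate_site_abundances <- function(species_ids,
                                     sites = paste0("site", 1:4),
                                     theta = 0.3, seed) {
  stopifnot(theta > 0, theta < 1)
  k <- length(species_ids)
  base_ab <- theta * (1 - theta)^(seq_len(k) - 1L)
  base_ab <- base_ab / sum(base_ab)
  local_seed(seed, {
    purrr::map_dfr(sites, function(s) {
      tibble(site = s, species_id = sample(species_ids),
             abundance = base_ab)
    })
  })
}

#' Simulate a multinomial ASV count table
#'
#' Draws reads for each sample as one multinomial of size `depth` over
#' ASVs.  Expected ASV proportions are the site's species abundances times a
#' per-species Dirichlet(1, ..., 1) split across that species' variant ASVs
#' (one split drawn per species, shared across samples).  Every sample
#' column sums exactly to `depth`, mirroring the fixed 50,000 clade-assigned
#' reads per sample of the study design.
#'
#' @param asvs An `asv_truth` tibble from [simulate_asv_variants()].
#' @param abundances A tibble from [simulate_site_abundances()] (its `site`
#'   values define the sites).
#' @param replicates_per_site Samples per site (default 3).
#' @param depth Reads per sample (default 50000).
#' @param seed Integer RNG seed.
#' @return An [asv_table]; sample names are `"<site>_r<replicate>"`.
#' @export
simulate_count_table <- function(asvs, abundances, replicates_per_site = 3,
                                 depth = 50000, seed) {
  stopifnot(depth >= 1, replicates_per_site >= 1)
  if (!all(asvs$species_id %in% abundances$species_id)) {
    abort("every simulated species needs an abundance at every site")
  }
  sites <- unique(abundances$site)
  local_seed(seed, {
    split_w <- asvs |>
      group_by(.data$species_id) |>
      mutate(w = {
        g <- rgamma(n(), shape = 1)
        g / sum(g)
      }) |>
      ungroup()
    counts <- matrix(
      0L, nrow(asvs), length(sites) * replicates_per_site,
      dimnames = list(
        asvs$asv_id,
        as.vector(outer(sites, seq_len(replicates_per_site),
                        function(s, r) paste0(s, "_r", r)))
      )
    )
    for (s in sites) {
      ab <- abundances[abundances$site == s, ]
      prob <- split_w$w * ab$abundance[match(split_w$species_id, ab$species_id)]
      draws <- rmultinom(replicates_per_site, depth, prob)
      counts[, paste0(s, "_r", seq_len(replicates_per_site))] <- draws
    }
    asv_table(setNames(asvs$sequence, asvs$asv_id), counts)
  })
}

#' Simulate a whole synthetic community with ground truth
#'
#' Convenience wrapper chaining [simulate_species_pool()],
#' [simulate_asv_variants()], [simulate_site_abundances()] and
#' [simulate_count_table()] under one seed.  The defaults reproduce the
#' study's design scale: 4 sites of 3 replicates at 50,000 reads each, 421-nt
#' amplicon inserts, within-species JC divergence at most 0.02 and
#' between-species divergence at least 0.10 (either side of the 0.04 species
#' cutoff).
#'
#' @param n_species Number of species (default 10).
#' @param length Marker length in nt (default 421).
#' @param min_between_jc,max_within_jc Between/within species JC bounds
#'   (defaults 0.10 and 0.02).
#' @param variants_per_species See [simulate_asv_variants()].
#' @param sites,replicates_per_site,depth Study design (defaults: 4 sites,
#'   3 replicates, 50000 reads).
#' @param theta Geometric rank-abundance parameter (default 0.3).
#' @param seed Integer RNG seed.
#' @return A list with elements `table` ([asv_table]), `truth`
#'   (`asv_truth` tibble), `abundances` and `pool`.
#' @export
simulate_community <- function(n_species = 10, length = 421,
                               min_between_jc = 0.10, max_within_jc = 0.02,
                               variants_per_species = c(1, 22),
                               sites = paste0("site", 1:4),
                               replicates_per_site = 3, depth = 50000,
                               theta = 0.3, seed) {
  seed <- as.integer(seed)
  pool <- simulate_species_pool(n_species, length, min_between_jc, seed = seed)
  truth <- simulate_asv_variants(pool, variants_per_species, max_within_jc,
                                 seed = seed + 1L)
  ab <- simulate_site_abundances(pool$species_id, sites, theta, seed = seed + 2L)
  tab <- simulate_count_table(truth, ab, replicates_per_site, depth,
                              seed = seed + 3L)
  list(table = tab, truth = truth, abundances = ab, pool = pool)
}

#' Simulate a gene-expression count table with a dominant operon
#'
#' Emulates an RNA-seq count table in which a small designated gene set (a
#' highly transcribed operon such as pmoCAB) jointly accounts for a fixed
#' fraction of total TPM in every sample, while the remaining transcript
#' abundance follows a log-normal.  Counts are Poisson draws around
#' length-weighted expected values, so the realized dominant share matches
#' the requested fraction to well within 2%.
#'
#' @param n_genes Total genes (>= 10; default 3774, a typical
#'   methanotroph-genome coding-gene count).
#' @param dominant_fraction Share of total TPM held by the dominant set, in
#'   `[0, 1)`.  The study's observed operon share was 12–32%.
#' @param n_samples Number of samples (default 3).
#' @param n_dominant Genes in the dominant set (default 3, an operon).
#' @param lib_size Expected aligned reads per sample (default 5e6).
#' @param sdlog Log-normal sd of non-dominant transcript abundance
#'   (default 1.2).
#' @param seed Integer RNG seed.
#' @return A tibble `gene_id`, `length_bp`, one count column per sample
#'   (`s1`, `s2`, ...), with attribute `dominant_genes`.
#' @export
simulate_expression_table <- function(n_genes = 3774, dominant_fraction = 0.2,
                                      n_samples = 3, n_dominant = 3,
                                      lib_size = 5e6, sdlog = 1.2, seed) {
  stopifnot(n_genes >= 10)
  if (dominant_fraction < 0 || dominant_fraction >= 1) {
    abort("`dominant_fraction` must be in [0, 1)")
  }
  local_seed(seed, {
    lengths <- sample(200:3000, n_genes, replace = TRUE)
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    dominant <- gene_id[seq_len(n_dominant)]
    counts <- vapply(seq_len(n_samples), function(s) {
      t_rest <- rlnorm(n_genes - n_dominant, meanlog = 0, sdlog = sdlog)
      t_rest <- t_rest / sum(t_rest) * (1 - dominant_fraction)
      g <- rgamma(n_dominant, shape = 5)
      t_dom <- g / sum(g) * dominant_fraction
      t_all <- c(t_dom, t_rest)  # relative transcript (TPM/1e6) abundance
      lambda <- t_all * lengths
      lambda <- lambda / sum(lambda) * lib_size
      rpois(n_genes, lambda)
    }, integer(n_genes))
    colnames(counts) <- paste0("s", seq_len(n_samples))
    out <- bind_cols(
      tibble(gene_id = gene_id, length_bp = lengths),
      as_tibble(counts)
    )
    attr(out, "dominant_genes") <- dominant
    out
  })
}
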