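#' Scenario configuration for the synthetic metacommunity generator
#'
#' Describes a landscape (sites, ecosystem layout, spatial extent), a
#' regional species pool, and an assembly regime, sufficient to regenerate a
#' dataset from a seed. Defaults emulate the study design the package is
#' aimed at: 11 sites (4 urban, 4 suburban, 3 forest parks) spanning about
#' 27 km, three composite samples per site (33 samples), tables rarefied to
#' 20,000 reads.
#'
#' @param n_sites Number of sites.
#' @param samples_per_site Samples per site.
#' @param ecosystem_layout Named integer vector giving the number of sites
#'   of each type, in spatial order from the urban end to the forest end.
#' @param extent_km Approximate maximum pairwise site distance (km).
#' @param depth Reads per sample.
#' @param n_taxa Regional pool size.
#' @param metacommunity Either `list(type = "logseries", x = <0..1>)` (the
#'   canonical log-series regional pool; `x` is the log-series parameter) or
#'   an explicit relative-abundance vector.
#' @param regime One of `"sloan-sampling"`, `"neutral-dynamics"`,
#'   `"niche-filtering"`, `"mixed"`.
#' @param Nm_true Immigration parameter for sloan sampling (may be `Inf`
#'   for the full-dispersal multinomial limit); also the dispersal knob of
#'   the mixed regime.
#' @param J,m,generations Local community size, migration rate and number of
#'   generations for zero-sum neutral dynamics.
#' @param niche List of niche-filtering parameters: `n_specialists`
#'   (planted narrow-niche taxa), `specialist_sigma`, `specialist_boost`
#'   (regional-share multiplier for planted taxa; locally-adapted taxa are
#'   locally dominant), `background_sigma` (range for unplanted niche
#'   widths), `frac_filtered` (fraction of taxa subject to filtering beyond
#'   the planted ones), `filtered_sigma` (range), `noise_sd` (lognormal sd
#'   on expected shares).
#' @param seed Integer master seed.
#' @return A validated object of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 11, samples_per_site = 3,
                            ecosystem_layout = c(urban = 4, suburban = 4,
                                                 forest = 3),
                            extent_km = 27, depth = 20000, n_taxa = 1000,
                            metacommunity = list(type = "logseries",
                                                 x = 0.9999),
                            regime = c("sloan-sampling", "neutral-dynamics",
                                       "niche-filtering", "mixed"),
                            Nm_true = 556, J = 1000, m = 0.5,
                            generations = 20,
                            niche = list(), seed = 1) {
  regime <- match.arg(regime)
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  if (sum(ecosystem_layout) != n_sites)
    stop("ecosystem_layout must sum to n_sites", call. = FALSE)
  if (!all(names(ecosystem_layout) %in% ecosystem_levels))
    stop("ecosystem_layout types must be drawn from ",
         paste(ecosystem_levels, collapse = "/"), call. = FALSE)
  if (extent_km <= 0) stop("extent_km must be positive", call. = FALSE)
  if (depth < 1 || samples_per_site < 1 || n_taxa < 2)
    stop("depth, samples_per_site and n_taxa must be positive", call. = FALSE)
  if (!(is.infinite(Nm_true) || Nm_true > 0))
    stop("Nm_true must be positive", call. = FALSE)
  if (m < 0 || m > 1) stop("m must lie in [0, 1]", call. = FALSE)
  niche_defaults <- list(n_specialists = 30, specialist_sigma = 0.25,
                         specialist_boost = 3, background_sigma = c(5, 10),
                         frac_filtered = 0, filtered_sigma = c(0.3, 0.6),
                         noise_sd = 0.05)
  unknown <- setdiff(names(niche), names(niche_defaults))
  if (length(unknown))
    stop("unknown niche parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  niche <- utils::modifyList(niche_defaults, niche)
  if (any(unlist(niche[c("specialist_sigma", "background_sigma",
                         "filtered_sigma")]) <= 0))
    stop("niche widths (sigma) must be positive", call. = FALSE)
  structure(list(n_sites = n_sites, samples_per_site = samples_per_site,
                 ecosystem_layout = ecosystem_layout, extent_km = extent_km,
                 depth = depth, n_taxa = n_taxa,
                 metacommunity = metacommunity, regime = regime,
                 Nm_true = Nm_true, J = J, m = m, generations = generations,
                 niche = niche, seed = seed),
            class = "scenario_config")
}

# Regional relative-abundance vector: log-series species-abundance draws
# (P(n) proportional to x^n / n), the canonical neutral-theory pool.
metacommunity_shares <- function(config) {
  mc <- config$metacommunity
  if (is.numeric(mc)) {
    if (length(mc) != config$n_taxa)
      stop("explicit metacommunity vector must have n_taxa entries",
           call. = FALSE)
    return(mc / sum(mc))
  }
  stopifnot(identical(mc$type, "logseries"), mc$x > 0, mc$x < 1)
  with_seed(derive_seed(config$seed, "metacommunity"), {
    nmax <- min(5e6, ceiling(log(1e-12) / log(mc$x)))
    pmf <- mc$x^seq_len(nmax) / seq_len(nmax)
    cdf <- cumsum(pmf / sum(pmf))
    ab <- findInterval(runif(config$n_taxa), cdf) + 1
    sort(ab, decreasing = TRUE) / sum(ab)
  })
}

scenario_sample_ids <- function(config) {
  sites <- sprintf("site%02d", seq_len(config$n_sites))
  paste0(rep(sites, each = config$samples_per_site), "_s",
         rep(seq_len(config$samples_per_site), config$n_sites))
}

#' Generate a synthetic landscape and its sample metadata
#'
#' Places sites along an urbanization gradient (urban clustered at one end,
#' forest at the other) so the maximum pairwise distance is close to the
#' configured extent, and draws soil chemistry from ecosystem-type-specific
#' distributions (forest soils more acidic and organic-rich; urban soils
#' enriched in total phosphorus and sulfur). An `urbanization` column holds
#' the scalar niche axis E (urban end +1, forest end -1, small within-site
#' jitter).
#'
#' @param config A [scenario_config()].
#' @return A [sample_metadata()] table with environmental columns and the
#'   urbanization axis.
#' @export
landscape <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(derive_seed(config$seed, "landscape"), {
    n <- config$n_sites
    types <- rep(names(config$ecosystem_layout), config$ecosystem_layout)
    x <- seq(0, config$extent_km, length.out = n)
    if (n > 2) x[2:(n - 1)] <- x[2:(n - 1)] +
      runif(n - 2, -0.02, 0.02) * config$extent_km
    y <- rnorm(n, 0, 0.02 * config$extent_km)
    lat0 <- 24.5
    lon0 <- 118.0
    site <- data.frame(
      site_id = sprintf("site%02d", seq_len(n)),
      ecosystem_type = types,
      longitude = lon0 + x / (111.19 * cos(lat0 * pi / 180)),
      latitude = lat0 + y / 111.19,
      E = 1 - 2 * x / config$extent_km,
      stringsAsFactors = FALSE)
    env_mean <- list(
      pH = c(urban = 6.8, suburban = 6.3, forest = 4.8),
      moisture = c(urban = 18, suburban = 22, forest = 28),
      TOC = c(urban = 18, suburban = 22, forest = 35),
      TN = c(urban = 1.4, suburban = 1.6, forest = 2.4),
      TP = c(urban = 0.90, suburban = 0.70, forest = 0.45),
      TS = c(urban = 0.35, suburban = 0.28, forest = 0.20))
    env_sd <- c(pH = 0.3, moisture = 3, TOC = 4, TN = 0.3, TP = 0.10,
                TS = 0.05)
    k <- config$samples_per_site
    df <- site[rep(seq_len(n), each = k), , drop = FALSE]
    df$sample_id <- scenario_sample_ids(config)
    df$longitude <- df$longitude + rnorm(nrow(df), 0, 0.05 / 111.19)
    df$latitude <- df$latitude + rnorm(nrow(df), 0, 0.05 / 111.19)
    df$urbanization <- pmax(-1.2, pmin(1.2, df$E + rnorm(nrow(df), 0, 0.05)))
    df$E <- NULL
    for (v in names(env_mean)) {
      mu <- env_mean[[v]][df$ecosystem_type]
      df[[v]] <- pmax(0.01, mu + rnorm(nrow(df), 0, env_sd[v]))
    }
    df$TC <- df$TOC + pmax(0, rnorm(nrow(df), 2, 0.5))
    df[["C:N"]] <- df$TC / df$TN
    rownames(df) <- NULL
    sample_metadata(df[, c("sample_id", "site_id", "ecosystem_type",
                           "longitude", "latitude", "urbanization",
                           "pH", "moisture", "TOC", "TN", "TC", "C:N",
                           "TP", "TS")])
  })
}

counts_from_shares <- function(shares, depth, ids, taxa) {
  counts <- t(apply(shares, 1, function(p)
    rmultinom(1, depth, p)[, 1]))
  dimnames(counts) <- list(ids, taxa)
  counts
}

synthetic_taxonomy <- function(taxa, seed) {
  with_seed(seed, {
    phyla <- paste0("Phylum", LETTERS[1:4])
    classes <- paste0("Class", LETTERS[1:8])
    ph <- sample(phyla, length(taxa), replace = TRUE)
    cl <- paste0(ph, "_", sample(classes, length(taxa), replace = TRUE))
    data.frame(kingdom = "Synthetica", phylum = ph, class = cl,
               row.names = taxa, stringsAsFactors = FALSE)
  })
}

#' Sample communities under the Sloan neutral model
#'
#' For each sample and taxon with metacommunity share p, a local relative
#' abundance is drawn from Beta(Nm p, Nm (1 - p)) (taxa are fully coupled to
#' the regional pool with immigration strength Nm), shares are renormalized,
#' and reads drawn by multinomial at the configured depth. `Nm_true = Inf`
#' gives the full-dispersal limit (multinomial sampling of the
#' metacommunity itself).
#'
#' @param config A [scenario_config()] with `regime = "sloan-sampling"`.
#' @param shares Optional metacommunity share vector (defaults to the
#'   configured pool).
#' @return A [community_table()] whose rows sum to `depth`.
#' @export
sample_sloan <- function(config, shares = metacommunity_shares(config)) {
  stopifnot(inherits(config, "scenario_config"))
  ids <- scenario_sample_ids(config)
  taxa <- sprintf("ASV%05d", seq_along(shares))
  bad <- shares <= 0 | shares >= 1
  if (any(bad)) {
    warning("skipping ", sum(bad), " taxa with share outside (0,1)",
            call. = FALSE)
    shares[bad] <- 0
  }
  counts <- with_seed(derive_seed(config$seed, "sloan"), {
    n <- length(ids)
    a <- matrix(0, n, length(shares))
    pos <- which(shares > 0)
    for (i in seq_len(n)) {
      if (is.infinite(config$Nm_true)) {
        a[i, pos] <- shares[pos]
      } else {
        a[i, pos] <- rbeta(length(pos), config$Nm_true * shares[pos],
                           config$Nm_true * (1 - shares[pos]))
      }
    }
    a <- a / rowSums(a)
    counts_from_shares(a, config$depth, ids, taxa)
  })
  community_table(counts,
                  taxonomy = synthetic_taxonomy(
                    taxa, derive_seed(config$seed, "taxonomy")))
}

#' Simulate zero-sum neutral dynamics (Hubbell-style drift)
#'
#' Each sample is a local community of J individuals initialized from the
#' metacommunity; every update kills one individual and replaces it from the
#' metacommunity with probability m, otherwise from the local community.
#' After `generations * J` updates, reads are drawn at depth from the final
#' local composition.
#'
#' @param config A [scenario_config()] with `regime = "neutral-dynamics"`.
#' @param shares Optional metacommunity share vector.
#' @return A [community_table()] whose rows sum to `depth`.
#' @export
simulate_neutral_dynamics <- function(config,
                                      shares = metacommunity_shares(config)) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$m < 0 || config$m > 1)
    stop("m must lie in [0, 1]", call. = FALSE)
  ids <- scenario_sample_ids(config)
  taxa <- sprintf("ASV%05d", seq_along(shares))
  counts <- with_seed(derive_seed(config$seed, "drift"), {
    meta_cum <- cumsum(shares)
    n_updates <- as.integer(config$generations * config$J)
    final <- matrix(0L, length(ids), length(shares))
    for (i in seq_along(ids)) {
      init <- rmultinom(1, config$J, shares)[, 1]
      local <- neutral_drift_cpp(as.integer(init), meta_cum, config$m,
                                 n_updates)
      final[i, ] <- rmultinom(1, config$depth, local / config$J)[, 1]
    }
    dimnames(final) <- list(ids, taxa)
    final
  })
  community_table(counts,
                  taxonomy = synthetic_taxonomy(
                    taxa, derive_seed(config$seed, "taxonomy")))
}

# Gaussian niche responses on the urbanization axis. Returns per-taxon
# optima/widths and the planted-specialist flag.
niche_params <- function(config, shares) {
  nt <- length(shares)
  np <- config$niche$n_specialists
  if (np > nt) stop("more planted specialists than taxa", call. = FALSE)
  with_seed(derive_seed(config$seed, "niche-params"), {
    sigma <- runif(nt, config$niche$background_sigma[1],
                   config$niche$background_sigma[2])
    mu <- runif(nt, -1.2, 1.2)
    planted <- logical(nt)
    # planted specialists take top abundance ranks (locally-adapted taxa are
    # locally dominant): their regional share is then high enough that the
    # neutral curve predicts near-full occupancy, while habitat confinement
    # keeps their observed occupancy near 1/3
    if (np > 0) {
      start <- min(2, nt - np + 1)
      planted[seq(start, length.out = np)] <- TRUE
      centers <- c(1, 0, -1) # urban, suburban, forest
      mu[planted] <- rep_len(centers, np)
      sigma[planted] <- config$niche$specialist_sigma
    }
    nf <- round(config$niche$frac_filtered * nt)
    if (nf > 0) {
      pool <- which(!planted)
      filt <- sample(pool, min(nf, length(pool)))
      sigma[filt] <- runif(length(filt), config$niche$filtered_sigma[1],
                           config$niche$filtered_sigma[2])
    }
    list(mu = mu, sigma = sigma, planted = planted)
  })
}

#' Simulate communities under Gaussian environmental (niche) filtering
#'
#' The expected share of taxon j in sample i is the metacommunity share
#' weighted by a Gaussian response exp(-(E_i - mu_j)^2 / (2 sigma_j^2)) on
#' the urbanization axis E and a lognormal noise term; counts are drawn by
#' multinomial at depth. Planted specialists get narrow widths tied to one
#' ecosystem type; as all widths grow large the model reduces to sloan-like
#' sampling with a large effective Nm.
#'
#' @param config A [scenario_config()] with `regime = "niche-filtering"` or
#'   `"mixed"`. In the mixed regime the niche-weighted shares are passed
#'   through Beta(Nm p, Nm (1-p)) sampling, so dispersal limitation
#'   (`Nm_true`) and selection (niche widths) act together.
#' @param meta Landscape metadata; defaults to [landscape()] of the config.
#' @param shares Optional metacommunity share vector.
#' @return A [community_table()] with attribute `truth`: data.frame(taxon_id,
#'   optimum, sigma, planted).
#' @export
simulate_niche_filtering <- function(config, meta = landscape(config),
                                     shares = metacommunity_shares(config)) {
  stopifnot(inherits(config, "scenario_config"))
  ids <- scenario_sample_ids(config)
  taxa <- sprintf("ASV%05d", seq_along(shares))
  E <- meta$urbanization[match(ids, meta$sample_id)]
  if (anyNA(E)) stop("metadata lacks urbanization axis for some samples",
                     call. = FALSE)
  pars <- niche_params(config, shares)
  if (any(pars$planted)) {
    # planted locally-adapted taxa are locally dominant: boost their
    # regional share so the neutral curve predicts near-full occupancy
    shares[pars$planted] <- shares[pars$planted] * config$niche$specialist_boost
    shares <- shares / sum(shares)
  }
  counts <- with_seed(derive_seed(config$seed, "niche"), {
    w <- outer(E, pars$mu, function(e, mu) e - mu)
    w <- exp(-(w^2) / (2 * matrix(pars$sigma^2, nrow = length(E),
                                  ncol = length(shares), byrow = TRUE)))
    expected <- sweep(w, 2, shares, "*") *
      rlnorm(length(w), 0, config$niche$noise_sd)
    expected <- expected / rowSums(expected)
    if (config$regime == "mixed" && is.finite(config$Nm_true)) {
      expected <- matrix(
        rbeta(length(expected), config$Nm_true * expected,
              config$Nm_true * (1 - expected)),
        nrow = nrow(expected))
      expected <- expected / rowSums(expected)
    }
    counts_from_shares(expected, config$depth, ids, taxa)
  })
  out <- community_table(counts,
                         taxonomy = synthetic_taxonomy(
                           taxa, derive_seed(config$seed, "taxonomy")))
  attr(out, "truth") <- data.frame(taxon_id = taxa, optimum = pars$mu,
                                   sigma = pars$sigma, planted = pars$planted,
                                   stringsAsFactors = FALSE)
  out
}

#' Default per-group regimes of the five-group mixed scenario
#'
#' Five taxonomic groups graded from dispersal-dominated (bacteria-like,
#' high Nm, no selection) to selection-dominated (invertebrate-like, strong
#' niche filtering with planted habitat specialists). Dispersal (Nm)
#' decreases and the niche-filtered fraction increases monotonically along
#' the gradient; bacteria-like and protist-like reuse the Nm magnitudes
#' reported for well-dispersed soil groups.
#'
#' @return data.frame of per-group regime parameters.
#' @export
mixed_group_defaults <- function() {
  data.frame(
    group = c("bacteria_like", "nematode_like", "protist_like",
              "fungus_like", "invertebrate_like"),
    Nm_true = c(556, 200, 82, 32, 40),
    frac_filtered = c(0, 0.06, 0.15, 0.25, 0.35),
    n_specialists = c(0, 0, 0, 0, 30),
    noise_sd = c(0.02, 0.22, 0.42, 0.60, 0.75),
    stringsAsFactors = FALSE)
}

#' Generate the five-group mixed scenario
#'
#' Emits one community table per taxonomic group over a shared landscape,
#' with regimes graded from dispersal-dominated to selection-dominated (see
#' [mixed_group_defaults()]), plus a truth record listing each taxon's
#' group, regime parameters and planted-specialist flag.
#'
#' @param config A [scenario_config()] (regime is forced to `"mixed"`); its
#'   `n_taxa` and `depth` apply per group.
#' @param groups data.frame of per-group parameters
#'   (default [mixed_group_defaults()]).
#' @return list(tables = named list of [community_table()]s, meta =
#'   [sample_metadata()], truth = data.frame, groups = the parameter table).
#' @export
mixed_scenario <- function(config = scenario_config(regime = "mixed",
                                                    n_taxa = 600),
                           groups = mixed_group_defaults()) {
  stopifnot(inherits(config, "scenario_config"))
  meta <- landscape(config)
  tables <- list()
  truth <- list()
  for (g in seq_len(nrow(groups))) {
    gname <- groups$group[g]
    gcfg <- config
    gcfg$regime <- "mixed"
    gcfg$Nm_true <- groups$Nm_true[g]
    gcfg$niche$frac_filtered <- groups$frac_filtered[g]
    gcfg$niche$n_specialists <- groups$n_specialists[g]
    gcfg$niche$noise_sd <- groups$noise_sd[g]
    gcfg$seed <- derive_seed(config$seed, "mixed-group", gname)
    tab <- simulate_niche_filtering(gcfg, meta = meta)
    tr <- attr(tab, "truth")
    tr$group <- gname
    tr$Nm_true <- groups$Nm_true[g]
    tables[[gname]] <- tab
    truth[[gname]] <- tr
  }
  list(tables = tables, meta = meta, truth = do.call(rbind, truth),
       groups = groups)
}
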