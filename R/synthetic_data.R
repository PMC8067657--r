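#' Parameters for a simulated 96-well enrichment-culture plate
#'
#' Defaults emulate the study conditions: up to 96 wells, each dominated by
#' its cyanobacterial host (host fraction 0.5-0.95 of reads) over a
#' heterotroph community of a few to ~two dozen members drawn from a global
#' pool, log-normal within-well proportions (few dominant, many rare
#' members), small cross-well leakage between plate neighbours, and
#' sequencing depths around 1e5 reads per well.
#'
#' @param n_wells number of occupied wells (<= 96).
#' @param pool_size number of heterotroph features in the global pool.
#' @param members_per_well inclusive integer range of heterotroph members.
#' @param host_fraction_range range of the host's read fraction, in (0,1).
#' @param abundance_shape log-normal sigma for within-well proportions.
#' @param leakage_range range of the per-adjacent-pair leakage fraction,
#'   within \[0, 0.5).
#' @param depth_range inclusive range of reads per well.
#' @param adjacency_scheme adjacency used for leakage, matching the filter's.
#' @param seed integer seed.
#' @return named list of validated parameters.
#' @export
plate_sim_params <- function(n_wells = 96L, pool_size = 300L,
                             members_per_well = c(2L, 24L),
                             host_fraction_range = c(0.5, 0.95),
                             abundance_shape = 1.5,
                             leakage_range = c(0.001, 0.02),
                             depth_range = c(5e4, 2e5),
                             adjacency_scheme = c("edge8", "edge4"),
                             seed = 1L) {
  adjacency_scheme <- match.arg(adjacency_scheme)
  if (n_wells > 96L) abort_fmt("n_wells must be <= 96")
  if (n_wells < 1L) abort_fmt("n_wells must be >= 1")
  if (max(members_per_well) > pool_size)
    abort_fmt("members_per_well cannot exceed pool_size")
  if (min(leakage_range) < 0 || max(leakage_range) >= 0.5)
    abort_fmt("leakage_range must lie within [0, 0.5)")
  if (min(depth_range) < 1) abort_fmt("depth_range must be positive")
  if (min(host_fraction_range) <= 0 || max(host_fraction_range) >= 1)
    abort_fmt("host_fraction_range must lie within (0,1)")
  list(n_wells = as.integer(n_wells), pool_size = as.integer(pool_size),
       members_per_well = as.integer(members_per_well),
       host_fraction_range = host_fraction_range,
       abundance_shape = abundance_shape, leakage_range = leakage_range,
       depth_range = depth_range, adjacency_scheme = adjacency_scheme,
       seed = as.integer(seed))
}

#' Simulate an enrichment-culture plate with cross-well leakage
#'
#' Each well holds one host feature plus its own heterotroph mixture; the
#' expected composition of a well is `(1 - sum(eps)) * own mixture + sum over
#' adjacent wells of eps * that well's own mixture`, with an independent
#' leakage fraction `eps` per ordered adjacent pair, and counts drawn
#' multinomially at the well's depth. Ground truth records true members,
#' contaminant entries (features leaked into wells where they are not true
#' members) and the realized leakage fractions.
#'
#' @param params a [plate_sim_params()] list.
#' @return list: `counts` (samples x features), `layout`, `taxonomy`,
#'   `truth` (list with `members`, `proportions`, `contaminants`, `leakage`,
#'   `host_feature`, `depths`).
#' @export
simulate_plate <- function(params = plate_sim_params()) {
  with_seed(params$seed, {
    n <- params$n_wells
    wells <- as.character(outer(1:12, LETTERS[1:8],
                                function(co, r) paste0(r, co)))
    wells <- wells[order(rep(1:8, each = 12), rep(1:12, 8))][seq_len(n)]
    samples <- sprintf("culture%02d", seq_len(n))
    layout <- plate_layout(samples, wells)
    het_pool <- sprintf("het%04d", seq_len(params$pool_size))
    host_genus <- sample(c("Prochlorococcus", "Synechococcus"), n, replace = TRUE)
    host_feat <- sprintf("host%02d", seq_len(n))
    features <- c(host_feat, het_pool)

    mpw <- params$members_per_well
    members <- vector("list", n)
    mixes <- matrix(0, n, length(features), dimnames = list(samples, features))
    for (i in seq_len(n)) {
      k <- sample(mpw[1L]:mpw[2L], 1L)
      mem <- sample(het_pool, k)
      w <- rlnorm(k, 0, params$abundance_shape)
      hf <- runif(1L, params$host_fraction_range[1L], params$host_fraction_range[2L])
      mixes[i, mem] <- (1 - hf) * w / sum(w)
      mixes[i, host_feat[i]] <- hf
      members[[i]] <- setNames((1 - hf) * w / sum(w), mem)
    }

    # leakage per ordered adjacent pair (receiver <- source)
    leak <- list()
    expected <- mixes
    for (i in seq_len(n)) {
      nb_wells <- adjacent_wells(wells[i], params$adjacency_scheme)
      nb <- which(wells %in% nb_wells)
      if (!length(nb)) next
      eps <- runif(length(nb), params$leakage_range[1L], params$leakage_range[2L])
      expected[i, ] <- (1 - sum(eps)) * mixes[i, ] +
        colSums(eps * mixes[nb, , drop = FALSE])
      leak[[samples[i]]] <- setNames(eps, samples[nb])
    }

    depths <- round(runif(n, params$depth_range[1L], params$depth_range[2L]))
    counts <- matrix(0L, n, length(features), dimnames = list(samples, features))
    for (i in seq_len(n))
      counts[i, ] <- rmultinom(1L, depths[i], expected[i, ])[, 1L]

    contaminants <- do.call(rbind, lapply(seq_len(n), function(i) {
      eps <- leak[[samples[i]]]
      if (is.null(eps)) return(NULL)
      do.call(rbind, lapply(names(eps), function(src) {
        j <- match(src, samples)
        if (eps[src] <= 0) return(NULL)
        feats <- c(names(members[[j]]), host_feat[j])
        feats <- setdiff(feats, names(members[[i]]))
        if (!length(feats)) return(NULL)
        data.frame(receiver = samples[i], source = src, feature_id = feats,
                   expected_leaked = unname(eps[src] * mixes[j, feats]),
                   stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(contaminants)) contaminants <- data.frame(
      receiver = character(), source = character(), feature_id = character(),
      expected_leaked = numeric(), stringsAsFactors = FALSE)

    tax <- taxonomy_table(
      features,
      kingdom = "Bacteria",
      phylum = c(rep("Cyanobacteria", n), rep("", params$pool_size)),
      genus = c(host_genus, rep("", params$pool_size)))
    truth <- list(members = setNames(members, samples),
                  proportions = mixes, expected = expected,
                  contaminants = contaminants, leakage = leak,
                  host_feature = setNames(host_feat, samples),
                  host_genus = setNames(host_genus, samples),
                  depths = setNames(depths, samples))
    list(counts = counts, layout = layout, taxonomy = tax, truth = truth)
  })
}

#' Mock-community design
#'
#' Eleven members combined either in equimolar concentrations or in a
#' two-fold dilution series (most concentrated member 2^(m-1) times the
#' least: 1024x for 11 members), with three technical replicates.
#'
#' @param member_ids feature ids of the mock members (default 11).
#' @param scheme `"equimolar"` or `"twofold_series"`.
#' @param replicates number of technical replicates.
#' @return list with `member_ids`, `scheme`, `replicates`, and `proportions`
#'   (intended proportions per member, identical across replicates).
#' @export
mock_design <- function(member_ids = sprintf("mock%02d", 1:11),
                        scheme = c("equimolar", "twofold_series"),
                        replicates = 3L) {
  scheme <- match.arg(scheme)
  m <- length(member_ids)
  if (m < 2L) abort_fmt("a mock design needs at least 2 members")
  w <- switch(scheme, equimolar = rep(1, m), twofold_series = 2^((m - 1):0))
  list(member_ids = member_ids, scheme = scheme,
       replicates = as.integer(replicates),
       proportions = setNames(w / sum(w), member_ids))
}

#' Simulate sequenced mock-community replicates
#'
#' Per replicate, counts are multinomial over the intended member
#' proportions plus injected spurious features, each with expected relative
#' abundance at most `contaminant_max_rel`.
#'
#' @param design a [mock_design()].
#' @param depth reads per replicate.
#' @param contaminant_max_rel upper bound on any contaminant's expected
#'   relative abundance, within \[0, 0.05).
#' @param n_contaminants number of spurious features injected per replicate.
#' @param seed integer seed.
#' @return list: `counts` (replicates x features) and `truth` (data.frame of
#'   injected contaminants with expected relative abundances).
#' @export
simulate_mock <- function(design = mock_design(), depth = 1e5,
                          contaminant_max_rel = 0.0015, n_contaminants = 3L,
                          seed = 1L) {
  if (contaminant_max_rel < 0 || contaminant_max_rel >= 0.05)
    abort_fmt("contaminant_max_rel must lie in [0, 0.05)")
  with_seed(seed, {
    members <- design$member_ids
    if (contaminant_max_rel == 0) n_contaminants <- 0L
    spurious <- if (n_contaminants > 0)
      sprintf("spurious%02d", seq_len(n_contaminants)) else character()
    features <- c(members, spurious)
    samples <- sprintf("%s_rep%d", design$scheme, seq_len(design$replicates))
    counts <- matrix(0L, length(samples), length(features),
                     dimnames = list(samples, features))
    truth <- list()
    for (r in seq_along(samples)) {
      crel <- if (n_contaminants > 0)
        runif(n_contaminants, contaminant_max_rel / 4, contaminant_max_rel) else numeric()
      p <- c(design$proportions * (1 - sum(crel)), setNames(crel, spurious))
      counts[r, ] <- rmultinom(1L, depth, p)[, 1L]
      if (length(crel))
        truth[[r]] <- data.frame(sample_id = samples[r], feature_id = spurious,
                                 expected_rel = unname(crel),
                                 stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(sample_id = character(), feature_id = character(),
                 expected_rel = numeric(), stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

#' Simulate a rooted feature phylogeny
#'
#' A random coalescent topology over the features with exponential-ish
#' coalescent branch lengths, deterministic per seed.
#'
#' @param feature_ids tip labels (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] rooted binary tree.
#' @export
simulate_tree <- function(feature_ids, seed = 1L) {
  if (length(feature_ids) < 2L) abort_fmt("need at least 2 features for a tree")
  with_seed(seed, ape::rcoal(length(feature_ids), tip.label = feature_ids))
}

#' Parameters for simulated ocean transect site tables
#'
#' Defaults emulate a global survey: 500 sites with surface-weighted depths
#' down to 5000 m; OTUs split into cosmopolitan / intermediate / sparse
#' occupancy archetypes (site-occupancy probabilities 0.9 / 0.5 / 0.05); host
#' (picocyanobacterial) read fractions that decay with depth; and one
#' designated OTU whose abundance is rank-coupled to the combined host
#' abundance at a target Spearman correlation via a Gaussian copula.
#'
#' @param n_sites number of sites.
#' @param n_otus_per_archetype named vector: OTUs per archetype.
#' @param occupancy named occupancy probabilities per archetype, ordered
#'   cosmopolitan > intermediate > sparse.
#' @param coupling_rho target Spearman correlation between the coupled OTU's
#'   relative abundance and the combined host fraction.
#' @param n_deep_otus extra OTUs restricted to sites below `deep_cut_m`
#'   (default 0), for depth-partition experiments.
#' @param deep_cut_m depth cut for the restricted OTUs.
#' @param depth_mean_m mean of the (truncated-exponential) site depths.
#' @param reads_per_site sequencing depth per site.
#' @param seed integer seed.
#' @return named list of validated parameters.
#' @export
site_sim_params <- function(n_sites = 500L,
                            n_otus_per_archetype = c(cosmopolitan = 10L,
                                                     intermediate = 10L,
                                                     sparse = 10L),
                            occupancy = c(cosmopolitan = 0.9,
                                          intermediate = 0.5,
                                          sparse = 0.05),
                            coupling_rho = 0.3,
                            n_deep_otus = 0L, deep_cut_m = 200,
                            depth_mean_m = 300, reads_per_site = 1e5,
                            seed = 1L) {
  if (!(occupancy["cosmopolitan"] > occupancy["intermediate"] &&
        occupancy["intermediate"] > occupancy["sparse"]))
    abort_fmt("occupancy must be ordered cosmopolitan > intermediate > sparse")
  if (abs(coupling_rho) > 0.99) abort_fmt("coupling_rho must lie in [-0.99, 0.99]")
  list(n_sites = as.integer(n_sites),
       n_otus_per_archetype = n_otus_per_archetype, occupancy = occupancy,
       coupling_rho = coupling_rho, n_deep_otus = as.integer(n_deep_otus),
       deep_cut_m = deep_cut_m, depth_mean_m = depth_mean_m,
       reads_per_site = reads_per_site, seed = as.integer(seed))
}

#' Simulate an ocean transect site table
#'
#' Produces per-site OTU counts, combined host-assigned counts and total
#' counts. The designated coupled OTU (the first cosmopolitan OTU, present at
#' every site) has log-abundance generated from the normal scores of the host
#' fraction through a Gaussian copula, so its rank correlation with host
#' abundance hits the configured target in expectation.
#'
#' @param params a [site_sim_params()] list.
#' @return list: `sites` (data.frame: site_id, latitude, longitude, depth_m,
#'   host_reads, total_reads), `counts` (sites x OTUs), `truth` (archetype
#'   per OTU, coupled OTU id, target rho, presence matrix).
#' @export
simulate_sites <- function(params = site_sim_params()) {
  with_seed(params$seed, {
    n <- params$n_sites
    arche <- rep(names(params$n_otus_per_archetype), params$n_otus_per_archetype)
    otus <- sprintf("otu%03d", seq_along(arche))
    if (params$n_deep_otus > 0) {
      deep <- sprintf("deep%03d", seq_len(params$n_deep_otus))
      otus <- c(otus, deep)
      arche <- c(arche, rep("deep", params$n_deep_otus))
    }
    names(arche) <- otus

    depth_m <- pmin(round(rexp(n, 1 / params$depth_mean_m)), 5000)
    sites <- data.frame(
      site_id = sprintf("site%03d", seq_len(n)),
      latitude = runif(n, -60, 60), longitude = runif(n, -180, 180),
      depth_m = depth_m, stringsAsFactors = FALSE)

    # host fraction: monotone in one latent normal that carries the depth decay
    u_host <- -depth_m / 500 + rnorm(n)
    host_frac <- 0.4 * stats::plogis(u_host - 1)

    coupled <- otus[arche == "cosmopolitan"][1L]
    present <- matrix(FALSE, n, length(otus),
                      dimnames = list(sites$site_id, otus))
    relmass <- matrix(0, n, length(otus), dimnames = dimnames(present))
    for (o in seq_along(otus)) {
      a <- arche[o]
      if (otus[o] == coupled) {
        present[, o] <- TRUE
        rho_p <- 2 * sin(pi * params$coupling_rho / 6)  # copula Pearson for target Spearman
        s <- qnorm((rank(host_frac, ties.method = "average") - 0.5) / n)
        z <- rho_p * s + sqrt(1 - rho_p^2) * rnorm(n)
        relmass[, o] <- exp(log(0.02) + 0.8 * z)
      } else if (a == "deep") {
        present[, o] <- depth_m > params$deep_cut_m &
          runif(n) < params$occupancy["intermediate"]
        relmass[present[, o], o] <- rlnorm(sum(present[, o]), log(0.005), 1)
      } else {
        present[, o] <- runif(n) < params$occupancy[[a]]
        relmass[present[, o], o] <- rlnorm(sum(present[, o]), log(0.005), 1)
      }
    }

    counts <- matrix(0L, n, length(otus), dimnames = dimnames(present))
    host_reads <- integer(n)
    total <- as.integer(rep(params$reads_per_site, n))
    for (i in seq_len(n)) {
      het <- relmass[i, ] / max(sum(relmass[i, ]), 1)  # fractions of non-host mass
      p <- c(host_frac[i], (1 - host_frac[i]) * het,
             max(0, (1 - host_frac[i]) * (1 - sum(het))))
      draw <- rmultinom(1L, total[i], p)[, 1L]
      host_reads[i] <- draw[1L]
      counts[i, ] <- draw[seq_along(otus) + 1L]
    }
    sites$host_reads <- host_reads
    sites$total_reads <- total
    list(sites = sites, counts = counts,
         truth = list(archetype = arche, coupled_otu = coupled,
                      target_rho = params$coupling_rho, presence = present))
  })
}
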