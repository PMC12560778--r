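#' Simulate a pure-birth community phylogeny
#'
#' Yule (pure-birth, rate 1) tree over `n_taxa` tips labelled
#' `ASV1..ASVn`, used as the stand-in phylogeny for synthetic
#' metacommunities.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @return A rooted `phylo` with positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 2) abort("need at least 2 taxa")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- paste0("ASV", seq_len(n_taxa))
  tree
}

#' Simulation parameters
#'
#' Parameter set for [simulate_metacommunity()]. The defaults emulate a
#' two-host, four-habitat-size amplicon survey at desk scale: 300 taxa,
#' 9 samples per host x habitat-size cell (72 samples), a log-normal
#' regional species-abundance distribution, read depths log-normal with
#' mean near 7000 (never below the rarefaction depth of 514), sites per
#' habitat size mirroring a 3/3/1/4 plot design, and moderate host
#' selection with strong dispersal mixing.
#'
#' * `selection_strength` (s): host-matching filter on a Brownian-motion
#'   host-affinity trait, so selection carries phylogenetic signal;
#'   `conservatism` in \[0, 1\] blends that trait with iid noise
#'   (1 = fully conserved).
#' * `habitat_selection`: same mechanism on an independent trait with
#'   opposite optima in small vs large habitats (variable selection).
#' * `uniform_selection`: selection toward one shared optimum in every
#'   sample (homogeneous selection).
#' * `dispersal_mixing` (m): fraction of each local community replaced by
#'   migrants from the well-mixed metacommunity average after local
#'   assembly; host-restricted taxa cannot establish on the wrong host.
#' * `drift_steps` / `pool_size`: each site's pool drifts from the
#'   regional pool by repeated multinomial resampling of `pool_size`
#'   individuals.
#' * `host_specific_fraction` (f): fraction of taxa planted as
#'   host-restricted indicators (boosted `indicator_boost`-fold, zero
#'   expected abundance in the non-target host).
#'
#' @param ... named overrides of the defaults listed above.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    n_taxa = 300,
    n_per_group = 9,
    hosts = c("C_surinamensis", "R_flaccida"),
    habitat_sizes = c("1-ha", "10-ha", "100-ha", "continuous"),
    sites_per_size = c(`1-ha` = 3, `10-ha` = 3, `100-ha` = 1, continuous = 4),
    pool_meanlog = 0,
    pool_sdlog = 1.2,
    conservatism = 1,
    selection_strength = 3,
    habitat_selection = 0,
    uniform_selection = 0,
    dispersal_mixing = 0.6,
    drift_steps = 12,
    pool_size = 2000,
    depth_meanlog = log(7000) - 0.8^2 / 2,
    depth_sdlog = 0.8,
    depth_min = 550,
    depth_max = 41000,
    host_specific_fraction = 0.05,
    indicator_boost = 15,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    abort("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  m <- p$dispersal_mixing
  if (m < 0 || m > 1) abort("dispersal_mixing must be in [0, 1]")
  if (p$selection_strength < 0) abort("selection_strength must be >= 0")
  if (p$conservatism < 0 || p$conservatism > 1)
    abort("conservatism must be in [0, 1]")
  f <- p$host_specific_fraction
  if (f < 0 || f > 1) abort("host_specific_fraction must be in [0, 1]")
  if (f > 0 && f * p$n_taxa < 1)
    abort("host_specific_fraction too small: f * n_taxa < 1")
  structure(p, class = "sim_params")
}

#' Named assembly scenarios
#'
#' Parameter presets whose dominant assembly regime is the named
#' process. `homogenizing_dispersal` is complete mixing without
#' selection; `variable_selection` imposes opposite habitat optima on a
#' phylogenetically conserved trait; `homogeneous_selection` selects
#' every sample toward one shared optimum; `dispersal_limitation`
#' isolates strongly drifted site pools; `drift` has weak mixing and
#' moderate site drift with no selection.
#'
#' @param name one of the five process names.
#' @param ... further overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
scenario <- function(name, ...) {
  presets <- list(
    homogenizing_dispersal = list(dispersal_mixing = 1, selection_strength = 0,
                                  habitat_selection = 0, uniform_selection = 0,
                                  drift_steps = 0, host_specific_fraction = 0),
    variable_selection = list(dispersal_mixing = 0, selection_strength = 0,
                              habitat_selection = 4, uniform_selection = 0,
                              drift_steps = 0, host_specific_fraction = 0),
    homogeneous_selection = list(dispersal_mixing = 0, selection_strength = 0,
                                 habitat_selection = 0, uniform_selection = 4,
                                 drift_steps = 15, pool_size = 1000,
                                 pool_sdlog = 0.7, host_specific_fraction = 0),
    dispersal_limitation = list(dispersal_mixing = 0.05, selection_strength = 0,
                                habitat_selection = 0, uniform_selection = 0,
                                drift_steps = 150, pool_size = 300,
                                host_specific_fraction = 0),
    drift = list(dispersal_mixing = 0.2, selection_strength = 0,
                 habitat_selection = 0, uniform_selection = 0,
                 drift_steps = 15, pool_size = 1000,
                 host_specific_fraction = 0)
  )
  if (!name %in% names(presets))
    abort("unknown scenario '%s'; valid names: %s", name,
          paste(names(presets), collapse = ", "))
  do.call(sim_params, c(presets[[name]], list(...)))
}

#' Simulate a host-associated metacommunity
#'
#' Generates a read-count matrix, sample metadata, phylogeny and
#' taxonomy with the statistical structure the analysis pipeline
#' assumes. Local communities are assembled multinomially from a
#' selection-weighted site pool, then a fraction `dispersal_mixing` of
#' each community is replaced by migrants from the metacommunity average
#' (host-restricted taxa cannot establish on the wrong host), and counts
#' are re-totalled to the drawn sequencing depth by largest-remainder
#' rounding.
#'
#' @param params a [sim_params()] object.
#' @return List with `counts` ([comm_matrix()]), `metadata`
#'   (data.frame), `tree` (`phylo`), `taxonomy` (data.frame), and the
#'   taxon ids of planted indicators per host in `planted`.
#' @export
simulate_metacommunity <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    tree <- ape::rphylo(p$n_taxa, birth = 1, death = 0)
    tree$tip.label <- paste0("ASV", seq_len(p$n_taxa))
    taxa <- tree$tip.label

    ## regional species-abundance distribution
    pool <- rlnorm(p$n_taxa, p$pool_meanlog, p$pool_sdlog)

    ## phylogenetically conserved traits (Brownian motion on the tree)
    zscore <- function(x) (x - mean(x)) / sd(x)
    ## conservatism blends a Brownian-motion trait with iid noise:
    ## 1 = fully phylogenetically conserved affinity, 0 = no signal
    bm_trait <- function() {
      w <- p$conservatism
      sqrt(w) * zscore(ape::rTraitCont(tree, model = "BM", sigma = 1)) +
        sqrt(1 - w) * zscore(rnorm(p$n_taxa))
    }
    host_trait <- bm_trait()
    hab_trait <- bm_trait()

    ## planted host-restricted indicators: the most extreme host-affinity
    ## taxa, so indicator blocks are phylogenetically coherent
    n_ind <- round(p$host_specific_fraction * p$n_taxa)
    planted <- list()
    host_only <- setNames(rep(NA_character_, p$n_taxa), taxa)
    if (n_ind >= 1) {
      nA <- ceiling(n_ind / 2)
      nB <- n_ind - nA
      ordA <- order(host_trait, decreasing = TRUE)
      planted[[p$hosts[1]]] <- taxa[ordA[seq_len(nA)]]
      ordB <- order(host_trait)
      planted[[p$hosts[2]]] <- if (nB > 0) taxa[ordB[seq_len(nB)]] else character(0)
      host_only[planted[[p$hosts[1]]]] <- p$hosts[1]
      host_only[planted[[p$hosts[2]]]] <- p$hosts[2]
      ## matched pool draws across the two blocks keep the planted mass
      ## balanced between hosts, so zeroing the wrong-host block does not
      ## create a diffuse compositional host signal in the other taxa
      idxA <- match(planted[[p$hosts[1]]], taxa)
      idxB <- match(planted[[p$hosts[2]]], taxa)
      k <- min(length(idxA), length(idxB))
      if (k > 0) pool[idxB[seq_len(k)]] <- pool[idxA[seq_len(k)]]
      boost_idx <- c(idxA, idxB)
      pool[boost_idx] <- pool[boost_idx] * p$indicator_boost
    }
    pool <- pool / sum(pool)

    ## sample frame: hosts x habitat sizes x sites
    sites <- unlist(lapply(names(p$sites_per_size), function(hs) {
      paste0(hs, "_site", seq_len(p$sites_per_size[[hs]]))
    }))
    site_size <- sub("_site[0-9]+$", "", sites)
    meta <- do.call(rbind, lapply(p$hosts, function(h) {
      do.call(rbind, lapply(p$habitat_sizes, function(hs) {
        ss <- sites[site_size == hs]
        data.frame(host = h, habitat_size = hs,
                   site = rep_len(ss, p$n_per_group))
      }))
    }))
    meta$habitat_class <- habitat_class(meta$habitat_size)
    meta$sample_id <- sprintf("S%03d", seq_len(nrow(meta)))
    meta <- meta[, c("sample_id", "host", "habitat_size", "habitat_class", "site")]
    n_samp <- nrow(meta)

    ## drifted site pools: repeated neutral multinomial resampling
    site_pool <- lapply(sites, function(s) {
      q <- pool
      for (k in seq_len(p$drift_steps)) {
        q <- rmultinom(1, p$pool_size, q)[, 1] / p$pool_size
      }
      q
    })
    names(site_pool) <- sites

    ## sequencing depths
    depth <- round(pmin(pmax(rlnorm(n_samp, p$depth_meanlog, p$depth_sdlog),
                             p$depth_min), p$depth_max))

    host_sign <- ifelse(meta$host == p$hosts[1], 1, -1)
    hab_sign <- ifelse(meta$habitat_class == "small", 1, -1)

    ## uniform (homogeneous) selection filters on membership of one
    ## focal clade - the infinitely conserved limit of a trait syndrome
    ## shared by a lineage - so the selected pool is phylogenetically
    ## tight by construction; the clade with the highest mean host
    ## affinity among those holding 15-35% of taxa is used
    unif_boost <- numeric(p$n_taxa)
    if (p$uniform_selection > 0) {
      clades <- ape::prop.part(tree)
      sizes <- lengths(clades)
      ok <- which(sizes >= 0.15 * p$n_taxa & sizes <= 0.35 * p$n_taxa)
      if (length(ok) == 0) ok <- which.min(abs(sizes - 0.25 * p$n_taxa))
      mean_tr <- vapply(clades[ok], function(tips) mean(host_trait[tips]),
                        numeric(1))
      focal <- clades[ok][[which.max(mean_tr)]]
      unif_boost[focal] <- p$uniform_selection
    }

    ## stage 1: local multinomial assembly from the selection-weighted
    ## site pool
    expected <- matrix(0, n_samp, p$n_taxa)
    for (i in seq_len(n_samp)) {
      e <- site_pool[[meta$site[i]]] *
        exp(p$selection_strength * host_sign[i] * host_trait +
            p$habitat_selection * hab_sign[i] * hab_trait +
            unif_boost)
      wrong <- !is.na(host_only) & host_only != meta$host[i]
      e[wrong] <- 0
      expected[i, ] <- e / sum(e)
    }
    local <- t(sapply(seq_len(n_samp), function(i) {
      rmultinom(1, depth[i], expected[i, ])[, 1]
    }))
    local_prop <- local / rowSums(local)

    ## stage 2: mass-effect exchange with the metacommunity average;
    ## host-restricted taxa are filtered out of the migrant pool
    migrant <- colMeans(local_prop)
    counts <- matrix(0L, n_samp, p$n_taxa,
                     dimnames = list(meta$sample_id, taxa))
    for (i in seq_len(n_samp)) {
      mig <- migrant
      wrong <- !is.na(host_only) & host_only != meta$host[i]
      mig[wrong] <- 0
      mig <- mig / sum(mig)
      mix <- (1 - p$dispersal_mixing) * local_prop[i, ] + p$dispersal_mixing * mig
      counts[i, ] <- round_to_total(mix, depth[i])
    }

    ## taxonomy: planted blocks get the two focal genus labels
    genera <- c("Nostoc", "Brasilonema", "Stigonema", "Tolypothrix",
                "Calothrix", "Scytonema", "Anabaena", "Desmonostoc",
                "Azotobacter", "Bradyrhizobium")
    tax <- data.frame(
      taxon_id = taxa,
      phylum = "Cyanobacteria",
      class = "Cyanophyceae",
      order = "Nostocales",
      family = "Nostocaceae",
      genus = sample(genera, p$n_taxa, replace = TRUE)
    )
    if (n_ind >= 1) {
      tax$genus[tax$taxon_id %in% planted[[p$hosts[1]]]] <- "Hassallia"
      tax$genus[tax$taxon_id %in% planted[[p$hosts[2]]]] <- "Fischerella"
      tax$family[tax$genus == "Hassallia"] <- "Tolypothrichaceae"
      tax$family[tax$genus == "Fischerella"] <- "Hapalosiphonaceae"
    }

    list(counts = comm_matrix(counts), metadata = meta, tree = tree,
         taxonomy = tax, planted = planted, params = p)
  })
}

#' Write a simulated dataset to TSV/Newick files
#'
#' @param sim result of [simulate_metacommunity()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_community_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write.table(sim$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$taxonomy, file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
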