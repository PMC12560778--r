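#' Pipeline configuration
#'
#' Flat configuration object for [run_pipeline()], with the
#' preprocessing, threshold and null-model defaults used throughout the
#' package (minimum depth 500 reads, rarefaction to 514, network
#' abundance filter 0.05%, edge thresholds p < 0.01 and q < 0.05, null
#' sizes 999/1000/1000/999 for beta-NTI / RC-Bray / IndVal / PERMANOVA,
#' robustness step 0.1 with 100 replicates). Round-trips losslessly to
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param counts,metadata,taxonomy,tree,outdir file paths (may be `NULL`
#'   when the pipeline is run on in-memory objects).
#' @param ... named overrides of the defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, taxonomy = NULL,
                            tree = NULL, outdir = NULL, ...) {
  cfg <- list(
    counts = counts, metadata = metadata, taxonomy = taxonomy,
    tree = tree, outdir = outdir,
    min_reads = 500, rarefy_depth = 514,
    min_abund = 5e-04, p_thresh = 0.01, q_thresh = 0.05,
    n_null_bnti = 999, n_null_rc = 1000, n_perm_indval = 1000,
    n_perm_permanova = 999,
    robustness_step = 0.1, robustness_reps = 100,
    indval_alpha = 0.01,
    assembly_group = "habitat_size",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$min_reads >= 0, cfg$rarefy_depth >= 1,
            cfg$min_abund >= 0, cfg$p_thresh > 0, cfg$p_thresh <= 1,
            cfg$q_thresh > 0, cfg$q_thresh <= 1,
            cfg$n_null_bnti >= 99, cfg$n_null_rc >= 1,
            cfg$robustness_step > 0, cfg$robustness_step <= 0.5)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, alpha/beta diversity with permutation tests,
#' indicator species analysis (host groups), assembly-process inference
#' (per habitat-size group), per-subset co-occurrence networks
#' (host x habitat class) and robustness simulation, writing all result
#' tables as TSV plus a JSON run manifest when `cfg$outdir` is set.
#' Reruns with the same config and seed give identical numeric output.
#'
#' Diversity and assembly stages use counts rarefied to
#' `cfg$rarefy_depth`; networks use relative abundances of the
#' unrarefied (depth-filtered) counts.
#'
#' @param cfg a [pipeline_config()].
#' @param data optional list with `counts` ([comm_matrix()]), `metadata`,
#'   `tree`, `taxonomy`; when omitted these are read from the paths in
#'   `cfg`.
#' @return List of stage results (`alpha`, `beta`, `indicator`,
#'   `assembly`, `networks`, `robustness`, `manifest`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), data = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if (is.null(data)) {
    for (f in c("counts", "metadata", "tree")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        abort("pipeline stage 'load' failed: missing input '%s'", f)
    }
    data <- list(counts = read_community_matrix(cfg$counts),
                 metadata = read_sample_metadata(cfg$metadata),
                 tree = ape::read.tree(cfg$tree),
                 taxonomy = if (!is.null(cfg$taxonomy))
                   read_taxonomy(cfg$taxonomy))
  }
  if (is.null(data$tree)) abort("phylogenetic metrics require a tree input")
  md <- data$metadata
  stages_done <- character(0)

  ## 1: preprocessing
  prep <- stage("prep", {
    filt <- filter_low_depth(data$counts, cfg$min_reads)
    rar <- rarefy(filt, cfg$rarefy_depth, seed = derive_seed(cfg$seed, 1))
    list(filtered = filt, rarefied = rar)
  })
  md <- md[match(rownames(prep$rarefied), md$sample_id), ]
  stages_done <- c(stages_done, "prep")

  ## 2: diversity
  div <- stage("diversity", {
    alpha <- alpha_diversity(prep$rarefied, data$tree)
    bc <- bray_curtis_matrix(to_relative(prep$rarefied))
    wu <- weighted_unifrac_matrix(prep$rarefied, data$tree)
    ord_bc <- pcoa(bc)
    tests <- rbind(
      data.frame(metric = "bray_curtis", factor = "host",
                 permanova(bc, md$host, cfg$n_perm_permanova,
                           derive_seed(cfg$seed, 21))),
      data.frame(metric = "bray_curtis", factor = "habitat_class",
                 permanova(bc, md$habitat_class, cfg$n_perm_permanova,
                           derive_seed(cfg$seed, 22))),
      data.frame(metric = "weighted_unifrac", factor = "host",
                 permanova(wu, md$host, cfg$n_perm_permanova,
                           derive_seed(cfg$seed, 23))))
    disp <- data.frame(metric = "bray_curtis", factor = "host",
                       permdisp(bc, md$host, cfg$n_perm_permanova,
                                derive_seed(cfg$seed, 24)))
    list(alpha = alpha, bray_curtis = bc, weighted_unifrac = wu,
         pcoa = ord_bc, permanova = tests, permdisp = disp)
  })
  stages_done <- c(stages_done, "diversity")

  ## 3: indicator species (host-specific taxa)
  ind <- stage("indicator", {
    indval(prep$rarefied, md$host, n_perm = cfg$n_perm_indval,
           seed = derive_seed(cfg$seed, 3), alpha = cfg$indval_alpha)
  })
  stages_done <- c(stages_done, "indicator")

  ## 4: assembly processes
  asm <- stage("assembly", {
    pairs <- assembly_pairs(prep$rarefied, data$tree,
                            n_null_bnti = cfg$n_null_bnti,
                            n_null_rc = cfg$n_null_rc,
                            seed = derive_seed(cfg$seed, 4))
    groups <- setNames(md[[cfg$assembly_group]], md$sample_id)
    list(pairs = pairs, fractions = process_fractions(pairs, groups))
  })
  stages_done <- c(stages_done, "assembly")

  ## 5: per-subset networks (host x habitat class)
  nets <- stage("network", {
    subsets <- split(md$sample_id, list(md$host, md$habitat_class), sep = " ")
    subsets <- subsets[lengths(subsets) >= 5]
    filt_rel <- to_relative(prep$filtered)
    out <- lapply(names(subsets), function(nm) {
      sub <- comm_matrix(cm_counts(filt_rel)[subsets[[nm]], , drop = FALSE])
      build_network(sub, min_mean_rel = cfg$min_abund,
                    p_thresh = cfg$p_thresh, q_thresh = cfg$q_thresh,
                    seed = derive_seed(cfg$seed, 5))
    })
    names(out) <- names(subsets)
    out
  })
  stages_done <- c(stages_done, "network")

  ## 6: robustness on each network with at least one edge
  rob <- stage("robustness", {
    out <- lapply(names(nets), function(nm) {
      net <- nets[[nm]]
      if (igraph::ecount(net$graph) == 0) return(NULL)
      cbind(network = nm,
            robustness_curves(net, step = cfg$robustness_step,
                              n_replicates = cfg$robustness_reps,
                              seed = derive_seed(cfg$seed, 6)))
    })
    do.call(rbind, out)
  })
  stages_done <- c(stages_done, "robustness")

  results <- list(prep = prep, diversity = div, indicator = ind,
                  assembly = asm, networks = nets, robustness = rob)
  results$manifest <- list(
    package_version = as.character(utils::packageVersion("phyllonet")),
    seed = cfg$seed,
    stages = stages_done,
    config_hash = digest_config(cfg),
    n_samples = nrow(prep$rarefied),
    n_taxa = ncol(prep$rarefied))
  if (!is.null(cfg$outdir)) emit_tables(results, cfg$outdir)
  results
}

digest_config <- function(cfg) {
  ## stable content hash without external dependencies
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Write pipeline result tables
#'
#' Emits the assembly-fraction table (processes x habitat groups, each
#' column summing to 100), per-network topology (including hub and
#' peripheral counts plus node/edge sharing), the key-species table (one
#' row per module hub; empty for hub-free networks), alpha diversity,
#' indicator results, robustness curves and a JSON manifest.
#'
#' @param results list returned by [run_pipeline()].
#' @param outdir output directory.
#' @return Character vector of files written, invisibly.
#' @export
emit_tables <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(df, name) {
    path <- file.path(outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  w(results$diversity$alpha, "alpha_diversity.tsv")
  w(results$diversity$permanova, "permanova.tsv")
  w(results$indicator, "indval.tsv")
  w(results$assembly$pairs, "assembly_pairs.tsv")
  w(results$assembly$fractions, "assembly_fractions.tsv")
  topo <- do.call(rbind, lapply(names(results$networks), function(nm) {
    cbind(network = nm, topology(results$networks[[nm]]))
  }))
  w(topo, "network_topology.tsv")
  keys <- do.call(rbind, lapply(names(results$networks), function(nm) {
    ks <- key_species(results$networks[[nm]])
    if (nrow(ks)) cbind(network = nm, ks)
  }))
  w(keys %||% data.frame(), "key_species.tsv")
  if (length(results$networks) >= 2) {
    cmp <- compare_networks(results$networks)
    w(cmp$unique, "network_unique.tsv")
    w(cmp$shared, "network_shared.tsv")
  }
  if (!is.null(results$robustness)) w(results$robustness, "robustness.tsv")
  jsonlite::write_json(results$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(outdir, "manifest.json"))
  invisible(files)
}
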