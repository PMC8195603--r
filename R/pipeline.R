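#' Default demo pipeline configuration
#'
#' A self-contained configuration that generates the synthetic fixture and
#' runs every stage on it: genome simulation, neighborhood scan with
#' clustering, architecture and retrieval networks, positional bias,
#' entropy/diversification, multicellularity enrichment, polydomain
#' scores, and a Z-score UPGMA tree.
#'
#' @param seed Master seed; every source of randomness derives from it.
#' @return A nested list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "neighborhoods", "archnet", "posbias",
               "entropy", "divtest", "enrich", "pds", "tree"),
    synthetic = list(n_taxa = 12L, family_divergence = 0.1),
    neighborhoods = list(window = 2L, max_gap = 50L, min_phyla = 2L,
                         L = 0.6, S = 0.8),
    posbias = list(n_arch = 100L, target_domain = "X",
                   position_probs = c(0.9, 0.05, 0.05)),
    entropy = list(n_rows = 20L, n_columns = 100L,
                   diversified_fraction = 0.5, k = 8L),
    pds = list(n_org = 50L, n_fam = 20L,
               expansions = list(list(organism = 1L, n_families = 5L,
                                      copies = 300L))),
    tree = list(n_structures = 6L)
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the contextual-analysis pipeline
#'
#' Executes the requested stages in dependency order on the synthetic
#' fixture defined by the configuration, writing every stage output plus a
#' manifest (seed, parameters, package version) into `out_dir`. Reruns with
#' the same configuration and seed produce byte-identical outputs.
#'
#' @param config Configuration list (see [demo_config()]) or the path of a
#'   YAML file holding one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  order_all <- c("simulate", "neighborhoods", "archnet", "posbias",
                 "entropy", "divtest", "enrich", "pds", "tree")
  unknown <- setdiff(stages, order_all)
  if (length(unknown)) stopf("unknown stage(s): %s", paste(unknown, collapse = ","))
  stages <- order_all[order_all %in% stages]
  deps <- list(neighborhoods = "simulate", enrich = c("simulate", "neighborhoods"))
  for (st in stages) {
    need <- setdiff(deps[[st]] %||% character(), stages)
    if (length(need))
      stopf("stage '%s' requires stage(s): %s", st, paste(need, collapse = ","))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  res <- list()

  if ("simulate" %in% stages) {
    sc_args <- config$synthetic %||% list()
    sc_args$seed <- derive_seed(seed, 1L)
    sc <- do.call(synthetic_config, sc_args)
    sim <- generate_genomes(sc)
    res$simulate <- sim
    ann_dir <- file.path(out_dir, "annotations")
    dir.create(ann_dir, showWarnings = FALSE)
    for (g in sim$genomes)
      write_annotation_table(g, file.path(ann_dir,
                                          paste0(g$taxon$taxon_id, ".tsv")))
    write_json_file(truth_as_json(sim$truth), file.path(out_dir, "truth.json"))
  }

  if ("neighborhoods" %in% stages) {
    p <- config$neighborhoods %||% list()
    sim <- res$simulate
    anchors <- vapply(sim$truth$cassettes, `[[`, character(1), "anchor_domain")
    nbs <- unlist(lapply(sim$genomes, extract_neighborhoods, anchor = anchors,
                         window = p$window %||% 2L), recursive = FALSE)
    nbs <- lapply(nbs, apply_validity_filters,
                  max_gap_nt = p$max_gap %||% 50L)
    groups <- find_conserved_groups(nbs, sim$genomes,
                                    L = p$L %||% 0.6, S = p$S %||% 0.8,
                                    min_phyla = p$min_phyla %||% 2L)
    res$neighborhoods <- list(neighborhoods = nbs, groups = groups,
                              recovery = evaluate_recovery(groups, sim$truth))
    write_json_file(groups_as_json(groups, res$neighborhoods$recovery),
                    file.path(out_dir, "groups.json"))
  }

  if ("archnet" %in% stages) {
    archs <- generate_architectures(60L, target_domain = "X",
                                    position_probs = c(0.6, 0.2, 0.2),
                                    seed = derive_seed(seed, 2L))
    net <- build_architecture_network(archs)
    res$archnet <- net
    el <- igraph::as_data_frame(net, what = "edges")
    write_tsv(el[order(el$from, el$to), ], file.path(out_dir, "archnet_edges.tsv"))
  }

  if ("posbias" %in% stages) {
    p <- config$posbias %||% list()
    archs <- generate_architectures(p$n_arch %||% 100L,
                                    target_domain = p$target_domain %||% "X",
                                    position_probs = p$position_probs,
                                    seed = derive_seed(seed, 3L))
    pc <- positional_counts(p$target_domain %||% "X", archs)
    test <- positional_bias_test(pc)
    res$posbias <- list(counts = pc, test = test)
    write_tsv(data.frame(domain = pc$domain, n_N = pc$n_Nterm,
                         n_int = pc$n_internal, n_C = pc$n_Cterm,
                         chi2 = test$chi2, p = test$p),
              file.path(out_dir, "posbias.tsv"))
  }

  if ("entropy" %in% stages || "divtest" %in% stages) {
    p <- config$entropy %||% list()
    ncol_ <- p$n_columns %||% 100L
    n_div <- round((p$diversified_fraction %||% 0.5) * ncol_)
    set.seed(derive_seed(seed, 4L))
    prof_div <- sample(c(rep("diversified", n_div),
                         rep("conserved", ncol_ - n_div)))
    prof_con <- sample(c(rep("diversified", max(2L, round(0.1 * ncol_))),
                         rep("conserved", ncol_ - max(2L, round(0.1 * ncol_)))))
    aln_div <- generate_alignment(p$n_rows %||% 20L, prof_div, k = p$k %||% 8L)
    aln_con <- generate_alignment(p$n_rows %||% 20L, prof_con, k = 2L)
    ep_div <- entropy_profile(aln_div, alignment_id = "diversified_family")
    ep_con <- entropy_profile(aln_con, alignment_id = "conserved_family")
    res$entropy <- list(diversified = ep_div, conserved = ep_con)
    write_tsv(data.frame(column_index = ep_div$columns_used, entropy = ep_div$H),
              file.path(out_dir, "entropy_diversified.tsv"))
    write_tsv(data.frame(column_index = ep_con$columns_used, entropy = ep_con$H),
              file.path(out_dir, "entropy_conserved.tsv"))
    if ("divtest" %in% stages) {
      dt <- mean_entropy_test(ep_div, ep_con)
      res$divtest <- dt
      write_json_file(dt, file.path(out_dir, "divtest.json"))
    }
  }

  if ("enrich" %in% stages) {
    sim <- res$simulate
    carriers <- sim$truth$cassettes[[1L]]$carriers
    taxa <- lapply(sim$genomes, `[[`, "taxon")
    inp <- trait_counts(carriers, taxa)
    pval <- hypergeom_upper_tail(inp)
    res$enrich <- list(input = inp, p = pval)
    write_json_file(list(q = inp$q, m = inp$m, n = inp$n, k = inp$k,
                         excluded_unknown = inp$excluded_unknown, p = pval),
                    file.path(out_dir, "enrich.json"))
  }

  if ("pds" %in% stages) {
    p <- config$pds %||% list()
    ct <- generate_count_table(p$n_org %||% 50L, p$n_fam %||% 20L,
                               expansion_spec = p$expansions %||% list(),
                               seed = derive_seed(seed, 5L))
    pds <- compute_pds(ct$counts)
    res$pds <- list(table = ct, result = pds)
    write_pds(pds, file.path(out_dir, "pds.tsv"))
  }

  if ("tree" %in% stages) {
    p <- config$tree %||% list()
    ns <- p$n_structures %||% 6L
    set.seed(derive_seed(seed, 6L))
    z <- matrix(stats::runif(ns * ns, 2, 20), ns, ns)
    z <- (z + t(z)) / 2
    diag(z) <- 30
    dimnames(z) <- list(sprintf("S%d", seq_len(ns)), sprintf("S%d", seq_len(ns)))
    tr <- upgma(zscores_to_distance(z))
    res$tree <- tr
    ape::write.tree(tr, file.path(out_dir, "tree.nwk"))
  }

  manifest <- list(package = "contextscan",
                   version = as.character(utils::packageVersion("contextscan")),
                   seed = seed, stages = stages,
                   parameters = config[setdiff(names(config),
                                               c("seed", "stages"))])
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(res)
}

#' Generate the bundled synthetic fixture and run every stage
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return Invisibly, the stage results of [run_pipeline()].
#' @export
demo_pipeline <- function(out_dir, seed = 1L) {
  run_pipeline(demo_config(seed), out_dir)
}

truth_as_json <- function(truth) {
  list(cassettes = lapply(truth$cassettes, function(cs)
    list(cassette_id = cs$cassette_id, families = cs$families,
         carriers = cs$carriers, phyla = cs$phyla,
         anchor_domain = cs$anchor_domain,
         inserted_genes = lapply(cs$inserted_genes, as.list))),
    biased_domains = truth$biased_domains,
    expansions = truth$expansions)
}

groups_as_json <- function(groups, recovery) {
  list(n_groups = length(groups),
       recovery = recovery,
       groups = lapply(groups, function(gr)
         list(taxa = unname(gr$taxa), phyla = gr$phyla,
              anchors = unname(vapply(gr$member_neighborhoods, `[[`,
                                      character(1), "anchor")),
              phyla_count = gr$filter_flags$phyla_count)))
}
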