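# Pipeline stage runners: each reads from a dataset directory laid out as in
# simulate_experiment() and writes TSV/JSON outputs into out_dir.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the risk-index stage
#'
#' Scores the dataset's metals table group by group and writes per-metal
#' contamination/risk factors (`risk.tsv`) and the per-group RI with its
#' level label (`risk_summary.json`).
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @param cfg configuration from [default_config()].
#' @return invisibly, the per-group summary list.
#' @export
stage_risk <- function(data_dir, out_dir, cfg = default_config()) {
  metals <- read_metals(file.path(data_dir, "metals.csv"))
  if (is.null(metals$group)) metals$group <- "all"
  targets <- unlist(cfg$ri_targets)
  per_metal <- list(); summary <- list()
  for (g in unique(metals$group)) {
    res <- ecological_risk_index(metals[metals$group == g, ], targets)
    per_metal[[g]] <- cbind(group = g, res$per_metal)
    summary[[g]] <- list(ri = res$ri, level = res$level)
  }
  write_tsv(do.call(rbind, per_metal), file.path(out_dir, "risk.tsv"))
  write_json_out(summary, file.path(out_dir, "risk_summary.json"))
  invisible(summary)
}

read_domain_table <- function(data_dir, dom)
  read_abundance_table(file.path(data_dir, paste0("otu_", dom, ".tsv")))

#' Run the diversity stage
#'
#' Per-sample alpha diversity (ACE, Shannon, Faith PD) with per-group ANOVA
#' letters, the abundant/rare partition, Bray-Curtis distances, PCoA
#' coordinates and PERMANOVA, for each domain present in the dataset.
#'
#' @inheritParams stage_risk
#' @return invisibly, a list of PERMANOVA results per domain.
#' @export
stage_diversity <- function(data_dir, out_dir, cfg = default_config()) {
  md <- read_metadata(file.path(data_dir, "metadata.csv"))
  out <- list()
  for (dom in c("bacteria", "fungi")) {
    tab <- read_domain_table(data_dir, dom)
    tree <- read_newick(file.path(data_dir, paste0("tree_", dom, ".nwk")))
    alpha <- alpha_diversity(tab, tree, rare_cutoff = cfg$ace_rare_cutoff)
    groups <- md$level[match(alpha$sample_id, md$sample_id)]
    alpha$level <- as.character(groups)
    write_tsv(alpha, file.path(out_dir, paste0("alpha_", dom, ".tsv")))
    letters_df <- do.call(rbind, lapply(c("ace", "shannon", "pd"), function(idx) {
      gc <- group_compare(alpha[[idx]], groups)
      cbind(index = idx, gc, anova_p = attr(gc, "anova_p"))
    }))
    write_tsv(letters_df, file.path(out_dir, paste0("alpha_letters_", dom, ".tsv")))
    part <- split_abundant_rare(tab, cfg$abundant_cutoff)
    write_tsv(data.frame(taxon = names(part$mean_relative_abundance),
                         mean_relative_abundance = part$mean_relative_abundance,
                         class = ifelse(names(part$mean_relative_abundance) %in%
                                          part$abundant, "abundant", "rare")),
              file.path(out_dir, paste0("abundant_rare_", dom, ".tsv")))
    d <- bray_curtis(tab)
    write_tsv(data.frame(sample_id = rownames(d), d, check.names = FALSE),
              file.path(out_dir, paste0("bray_", dom, ".tsv")))
    ord <- pcoa(d)
    write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates[, 1:min(4, ncol(ord$coordinates))],
                         check.names = FALSE),
              file.path(out_dir, paste0("pcoa_", dom, ".tsv")))
    pm <- permanova(d, groups, n_perm = cfg$permanova_permutations,
                    seed = fork_seed(cfg$seed, paste0("permanova_", dom)))
    write_json_out(unclass(pm), file.path(out_dir, paste0("permanova_", dom, ".json")))
    out[[dom]] <- pm
  }
  invisible(out)
}

#' Run the metabolic-profiling stage
#'
#' Corrects every sample's ECO and FF plates, then writes the AWCD time
#' series, functional diversity indices (H', D, U) and substrate-group
#' intensities at the reading time of record, with per-group ANOVA letters
#' on AWCD.
#'
#' @inheritParams stage_risk
#' @return invisibly, the per-sample AWCD data.frame.
#' @export
stage_metabolic <- function(data_dir, out_dir, cfg = default_config()) {
  md <- read_metadata(file.path(data_dir, "metadata.csv"))
  rows <- list(); fd <- list(); gi <- list()
  for (i in seq_len(nrow(md))) {
    sid <- md$sample_id[i]
    for (kind in c("ECO", "FF")) {
      f <- file.path(data_dir, "plates", paste0(sid, "_", kind, ".csv"))
      if (!file.exists(f)) next
      prof <- correct_od(read_plate(f, kind))
      series <- vapply(prof$times, function(t) awcd(prof, t), numeric(1))
      rows[[paste(sid, kind)]] <- data.frame(
        sample_id = sid, level = md$level[i], kind = kind,
        time = prof$times, awcd = series, stringsAsFactors = FALSE)
      div <- functional_diversity(prof, cfg$awcd_time)
      fd[[paste(sid, kind)]] <- data.frame(
        sample_id = sid, level = md$level[i], kind = kind,
        H = div[["H"]], D = div[["D"]], U = div[["U"]])
      g <- substrate_group_intensity(prof, time = cfg$awcd_time)
      gi[[paste(sid, kind)]] <- data.frame(
        sample_id = sid, level = md$level[i], kind = kind,
        group = names(g), intensity = as.numeric(g))
    }
  }
  awcd_df <- do.call(rbind, rows); rownames(awcd_df) <- NULL
  write_tsv(awcd_df, file.path(out_dir, "awcd.tsv"))
  write_tsv(do.call(rbind, fd), file.path(out_dir, "functional_diversity.tsv"))
  write_tsv(do.call(rbind, gi), file.path(out_dir, "substrate_groups.tsv"))
  final <- awcd_df[awcd_df$time == cfg$awcd_time, ]
  letters_df <- do.call(rbind, lapply(split(final, final$kind), function(dd) {
    gc <- group_compare(dd$awcd, dd$level)
    cbind(kind = dd$kind[1], gc, anova_p = attr(gc, "anova_p"))
  }))
  write_tsv(letters_df, file.path(out_dir, "awcd_letters.tsv"))
  invisible(awcd_df)
}

#' Run the functional-gene stage
#'
#' Applies the amplification-efficiency filter, quantifies relative copy
#' numbers against the CT detection limit, and writes per-gene abundances
#' plus per-cycle (C/N/P/S) sums with group comparisons.
#'
#' @inheritParams stage_risk
#' @return invisibly, the `gene_abundance`.
#' @export
stage_genes <- function(data_dir, out_dir, cfg = default_config()) {
  genes <- read_gene_ct(file.path(data_dir, "genes_ct.csv"))
  eff_f <- file.path(data_dir, "gene_efficiency.csv")
  if (file.exists(eff_f)) {
    eff <- utils::read.csv(eff_f)
    keep <- efficiency_filter(stats::setNames(eff$efficiency, eff$gene),
                              cfg$efficiency_range)
    keep <- intersect(rownames(genes$ct), keep)
    genes$ct <- genes$ct[keep, , drop = FALSE]
    genes$cycle <- genes$cycle[keep]
  }
  ab <- qmec_quantify(genes, detection_ct = cfg$detection_ct)
  write_tsv(data.frame(gene = rownames(ab$copies), cycle = ab$cycle,
                       ab$copies, check.names = FALSE),
            file.path(out_dir, "gene_abundance.tsv"))
  md <- read_metadata(file.path(data_dir, "metadata.csv"))
  groups <- md$level[match(colnames(ab$copies), md$sample_id)]
  cs <- cycle_summaries(ab, groups)
  write_tsv(data.frame(category = rownames(cs$per_category), cs$per_category,
                       check.names = FALSE),
            file.path(out_dir, "cycle_sums.tsv"))
  write_tsv(cs$group_letters, file.path(out_dir, "cycle_letters.tsv"))
  invisible(ab)
}

run_domain_network <- function(tab, domains, cfg, seed_tag, out_dir, label) {
  red <- filter_taxa(tab, cfg$network_min_abundance)
  cm <- correlation_matrix(red)
  scan <- seq(cfg$rmt_scan[["from"]], cfg$rmt_scan[["to"]], cfg$rmt_scan[["by"]])
  s <- suppressWarnings(rmt_threshold(cm, scan, cfg$rmt_fallback))
  net <- build_network(cm, as.numeric(s), domains = domains,
                       seed = fork_seed(cfg$seed, paste0("modules_", seed_tag)))
  topo <- suppressMessages(topology(net))
  roles <- zi_pi(net)
  stab <- stability(net, cfg$robustness_fraction, cfg$robustness_iterations,
                    seed = fork_seed(cfg$seed, paste0("robust_", seed_tag)))
  ends <- igraph::ends(net$graph, igraph::E(net$graph))
  write_tsv(data.frame(source = ends[, 1], target = ends[, 2],
                       weight = igraph::E(net$graph)$r,
                       sign = igraph::E(net$graph)$sign),
            file.path(out_dir, paste0("edges_", label, ".tsv")))
  nd <- data.frame(node = igraph::V(net$graph)$name,
                   module = unname(net$membership[igraph::V(net$graph)$name]))
  if (!is.null(igraph::V(net$graph)$domain))
    nd$domain <- igraph::V(net$graph)$domain
  write_tsv(nd, file.path(out_dir, paste0("nodes_", label, ".tsv")))
  write_tsv(roles, file.path(out_dir, paste0("zipi_", label, ".tsv")))
  report <- c(unclass(topo), list(threshold = as.numeric(s)), unclass(stab),
              list(keystone_count = sum(roles$keystone)))
  write_json_out(report, file.path(out_dir, paste0("network_", label, ".json")))
  list(net = net, topo = topo, stab = stab, roles = roles)
}

#' Run the co-occurrence network stage
#'
#' Builds RMT-thresholded networks for bacteria, fungi and the combined
#' bacterial-fungal community (node/edge lists, topology, Zi-Pi roles,
#' robustness/vulnerability), records interdomain positive-edge ratios, and
#' couples filtered bacterial taxa to functional genes when a CT table is
#' present.
#'
#' @inheritParams stage_risk
#' @return invisibly, a list of network results per label.
#' @export
stage_network <- function(data_dir, out_dir, cfg = default_config()) {
  tb <- read_domain_table(data_dir, "bacteria")
  tf <- read_domain_table(data_dir, "fungi")
  out <- list()
  domb <- stats::setNames(rep("bacteria", ncol(tb$counts)), taxon_ids(tb))
  domf <- stats::setNames(rep("fungi", ncol(tf$counts)), taxon_ids(tf))
  out$bacteria <- run_domain_network(tb, domb, cfg, "bacteria", out_dir, "bacteria")
  out$fungi <- run_domain_network(tf, domf, cfg, "fungi", out_dir, "fungi")
  comb <- abundance_table(cbind(tb$counts, tf$counts[rownames(tb$counts), ]))
  out$combined <- run_domain_network(comb, c(domb, domf), cfg, "combined",
                                     out_dir, "combined")
  ratios <- edge_domain_ratios(out$combined$net)
  write_json_out(as.list(ratios), file.path(out_dir, "edge_domain_ratios.json"))
  ct_path <- file.path(data_dir, "genes_ct.csv")
  if (file.exists(ct_path)) {
    ab <- qmec_quantify(read_gene_ct(ct_path), cfg$detection_ct)
    redb <- filter_taxa(tb, max(cfg$network_min_abundance, 1e-3))
    tg <- taxon_gene_network(redb, ab, threshold = 0.6,
                             seed = fork_seed(cfg$seed, "taxon_gene"))
    ends <- igraph::ends(tg$graph, igraph::E(tg$graph))
    write_tsv(data.frame(source = ends[, 1], target = ends[, 2],
                         weight = igraph::E(tg$graph)$r,
                         sign = igraph::E(tg$graph)$sign),
              file.path(out_dir, "edges_taxon_gene.tsv"))
    write_json_out(list(top_taxon = tg$top_taxon,
                        nodes = igraph::vcount(tg$graph),
                        edges = igraph::ecount(tg$graph)),
                   file.path(out_dir, "taxon_gene_summary.json"))
    out$taxon_gene <- tg
  }
  invisible(out)
}

#' Run the community-assembly stage
#'
#' Fits the Sloan neutral community model per domain over all samples and
#' computes the modified stochasticity ratio per treatment group, writing
#' fit JSONs, per-taxon prediction tables and pairwise MST values.
#'
#' @inheritParams stage_risk
#' @return invisibly, a list with `ncm` and `mst` results per domain.
#' @export
stage_assembly <- function(data_dir, out_dir, cfg = default_config()) {
  md <- read_metadata(file.path(data_dir, "metadata.csv"))
  out <- list()
  for (dom in c("bacteria", "fungi")) {
    tab <- read_domain_table(data_dir, dom)
    fit <- ncm_fit(tab)
    write_json_out(list(m = fit$m, nm = fit$nm, n = fit$n, r2 = fit$r2),
                   file.path(out_dir, paste0("ncm_", dom, ".json")))
    write_tsv(fit$taxa, file.path(out_dir, paste0("ncm_taxa_", dom, ".tsv")))
    groups <- md$level[match(sample_ids(tab), md$sample_id)]
    mst_rows <- list(); mst_sum <- list()
    for (g in levels(droplevels(groups))) {
      sub <- abundance_table(tab$counts[groups == g, , drop = FALSE])
      res <- mst(sub, n_null = cfg$mst_null_draws,
                 seed = fork_seed(cfg$seed, paste("mst", dom, g)),
                 d_max = cfg$mst_d_max)
      mst_rows[[g]] <- cbind(level = g, res$pairwise)
      mst_sum[[g]] <- list(mean = res$mean,
                           classification = res$classification)
    }
    write_tsv(do.call(rbind, mst_rows),
              file.path(out_dir, paste0("mst_", dom, ".tsv")))
    write_json_out(mst_sum, file.path(out_dir, paste0("mst_", dom, ".json")))
    out[[dom]] <- list(ncm = fit, mst = mst_sum)
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `risk`, `diversity`,
#' `metabolic`, `genes`, `network`, `assembly` (individual stages), and
#' `all` (the full pipeline). Options: `--seed <int>`, `--data <dir>`
#' (dataset directory; stages), `--out <dir>` (output directory),
#' `--config <yaml>`.
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly: 0 on success, 1 on error, 2 on usage
#'   error.
#' @export
run_cli <- function(argv) {
  usage <- paste(
    "usage: ecorisknet <simulate|risk|diversity|metabolic|genes|network|assembly|all>",
    "  [--seed N] [--data DIR] [--out DIR] [--config FILE]", sep = "\n")
  stages <- c("risk", "diversity", "metabolic", "genes", "network", "assembly")
  if (length(argv) == 0 || !argv[1] %in% c(stages, "simulate", "all")) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- argv[1]; argv <- argv[-1]
  opt <- list(seed = NULL, data = NULL, out = "ecorisknet_out", config = NULL)
  i <- 1
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opt) || i == length(argv)) {
      message("unknown or valueless option: ", argv[i], "\n", usage)
      return(invisible(2L))
    }
    opt[[key]] <- argv[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    cfg <- default_config(opt$config)
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    message(sprintf("[ecorisknet] %s  seed=%d  out=%s", cmd, cfg$seed, opt$out))
    if (cmd == "simulate") {
      simulate_experiment(seed = cfg$seed, dir = opt$out)
    } else {
      if (is.null(opt$data)) stop("--data <dir> is required for stage '", cmd, "'")
      if (!dir.exists(opt$data)) stop("no such dataset directory: ", opt$data)
      todo <- if (cmd == "all") stages else cmd
      for (st in todo) {
        message("[ecorisknet] running stage: ", st)
        get(paste0("stage_", st))(opt$data, opt$out, cfg)
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
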