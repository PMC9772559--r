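#' Read a rooted phylogenetic tree from a newick file or string
#'
#' Thin wrapper around [ape::read.tree()] that enforces a single tree and the
#' presence of branch lengths (missing lengths are set to 0 with a warning),
#' as required by Faith PD.
#'
#' @param path path to a newick file, or a newick string ending in `;`.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else {
    if (!file.exists(path)) stop("no such file: ", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close)
    stop("malformed newick: unbalanced parentheses")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("newick parse failure: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse failure")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, got several")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree
}

#' Depth of a tip: sum of branch lengths from the tip to the root
#' @param tree an [ape::phylo] object
#' @param tip tip label
#' @return numeric depth in branch-length units
#' @export
tip_depth <- function(tree, tip) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("tip not in tree: ", tip)
  root <- ape::Ntip(tree) + 1L
  depth <- 0
  node <- i
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    depth <- depth + tree$edge.length[e]
    node <- tree$edge[e, 1]
  }
  depth
}

#' Bundled Biolog substrate scheme
#'
#' Returns the packaged substrate-group scheme for a plate kind: the ECO
#' plate carries 31 substrates in triplicate plus 3 water controls, grouped
#' into carbohydrates (12), amino acids (6), polymers (4), carboxylic acids
#' (5), amines (2) and phenolic compounds (2); the FF plate carries 95
#' substrates plus 1 water control, grouped into carbohydrates (29),
#' carboxylic acids (20), amino acids (10), glycosides (4), polymers (5),
#' polyols (10), amines and amides (9) and miscellaneous (8).
#'
#' @param kind `"ECO"` or `"FF"`.
#' @return data.frame with columns `well`, `substrate`, `group`, `replicate`;
#'   control wells have group `"control"`.
#' @export
substrate_scheme <- function(kind = c("ECO", "FF")) {
  kind <- match.arg(kind)
  f <- system.file("extdata",
                   if (kind == "ECO") "biolog_eco_scheme.csv" else "biolog_ff_scheme.csv",
                   package = "ecorisknet", mustWork = TRUE)
  sc <- utils::read.csv(f, stringsAsFactors = FALSE)
  sc$kind <- kind
  sc
}

#' Read a raw Biolog plate file
#'
#' @param path CSV whose first column `well` holds 96 well labels (A1..H12)
#'   and whose remaining columns are optical densities at the timepoints
#'   named in the header (hours).
#' @param kind plate kind, `"ECO"` or `"FF"`; wells are validated against the
#'   bundled scheme.
#' @return a `raw_plate`: list with `kind`, `od` (wells x timepoints matrix)
#'   and `times` (hours, ascending).
#' @export
read_plate <- function(path, kind = c("ECO", "FF")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "well") stop("first column must be 'well'")
  sc <- substrate_scheme(kind)
  unknown <- setdiff(df$well, sc$well)
  if (length(unknown))
    stop("well label(s) not in the ", kind, " scheme: ",
         paste(unknown, collapse = ", "))
  times <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(times)) stop("timepoint columns must be numeric hours")
  if (is.unsorted(times, strictly = TRUE))
    stop("timepoints must be strictly ascending")
  od <- as.matrix(df[-1])
  rownames(od) <- df$well
  colnames(od) <- times
  structure(list(kind = kind, od = od, times = times), class = "raw_plate")
}

#' Bundled functional-gene catalog
#'
#' The packaged catalog of qPCR chip target genes and the biogeochemical
#' cycle (C, N, P or S) each reports on.
#'
#' @return data.frame with columns `gene` and `cycle`.
#' @export
gene_catalog <- function() {
  f <- system.file("extdata", "qmec_gene_catalog.csv",
                   package = "ecorisknet", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Read a gene x sample threshold-cycle (CT) table
#'
#' Blank cells are taken as non-detected amplifications. Genes absent from
#' the catalog are retained with cycle category `"unknown"` and a warning.
#'
#' @param path CSV whose first column `gene` names the target gene and whose
#'   remaining columns are samples; entries are CT values (positive) or blank.
#' @param catalog data.frame mapping `gene` to `cycle`; defaults to the
#'   bundled [gene_catalog()].
#' @return a `gene_ct`: list with `ct` (gene x sample matrix, NA =
#'   non-detected) and `cycle` (named character vector of categories).
#' @export
read_gene_ct <- function(path, catalog = gene_catalog()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be 'gene'")
  genes <- df$gene
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  ct <- as.matrix(df[-1])
  if (!is.numeric(ct)) storage.mode(ct) <- "double"
  rownames(ct) <- genes
  if (any(ct <= 0, na.rm = TRUE)) stop("CT values must be positive")
  cycle <- stats::setNames(catalog$cycle[match(genes, catalog$gene)], genes)
  if (anyNA(cycle)) {
    warning("gene(s) absent from catalog, category set to 'unknown': ",
            paste(genes[is.na(cycle)], collapse = ", "))
    cycle[is.na(cycle)] <- "unknown"
  }
  structure(list(ct = ct, cycle = cycle), class = "gene_ct")
}

#' Read a metals table
#'
#' @param path CSV with columns `metal`, `concentration`, `background`,
#'   `toxicity_factor`, and optionally `group`.
#' @return data.frame validated for positive backgrounds and toxicity factors.
#' @export
read_metals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metal", "concentration", "background", "toxicity_factor")
  if (!all(need %in% names(df)))
    stop("metals table must have columns: ", paste(need, collapse = ", "))
  if (any(df$background <= 0)) stop("background concentrations must be > 0")
  if (any(df$toxicity_factor <= 0)) stop("toxicity factors must be > 0")
  if (any(df$concentration < 0)) stop("concentrations must be >= 0")
  df
}

#' Fork a stage-specific seed from the master seed
#'
#' All randomness in the pipeline flows from one master seed; each stage
#' draws from a stream derived deterministically from the master seed and
#' the stage's name, so stages are reproducible independently of execution
#' order.
#'
#' @param seed master seed (integer).
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
fork_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Default pipeline configuration
#'
#' Thresholds and algorithm parameters for every stage, overridable from a
#' YAML file. Counts are validated positive and fractions to lie in (0,1).
#'
#' @param path optional YAML file whose top-level keys override defaults.
#' @return named list of parameters.
#' @export
default_config <- function(path = NULL) {
  cfg <- list(
    seed = 1L,
    # risk design
    ri_targets = c(L = 100, M = 200, H = 400),
    # diversity
    permanova_permutations = 999L,
    ace_rare_cutoff = 10L,
    abundant_cutoff = 0.01,
    # metabolic / genes
    awcd_time = 168,
    efficiency_range = c(1.8, 2.2),
    detection_ct = 31,
    # network
    network_min_abundance = 1e-4,
    rmt_scan = c(from = 0.30, to = 0.95, by = 0.01),
    rmt_fallback = 0.80,
    robustness_fraction = 0.5,
    robustness_iterations = 100L,
    # assembly
    mst_null_draws = 100L,
    mst_d_max = 1
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  stopifnot(cfg$permanova_permutations > 0, cfg$robustness_iterations > 0,
            cfg$mst_null_draws > 0,
            cfg$robustness_fraction > 0, cfg$robustness_fraction < 1,
            cfg$abundant_cutoff > 0, cfg$abundant_cutoff < 1,
            cfg$network_min_abundance > 0, cfg$network_min_abundance < 1)
  cfg
}
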