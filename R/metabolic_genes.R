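#' Control-correct a raw Biolog plate
#'
#' Averages replicate wells per substrate (ECO plates carry each substrate
#' in triplicate), subtracts the mean water-control absorbance at every
#' timepoint, and floors negative corrected values at 0.
#'
#' @param plate a `raw_plate` from [read_plate()].
#' @param scheme substrate scheme from [substrate_scheme()]; defaults to the
#'   bundled scheme for the plate's kind.
#' @return a `plate_profile`: list with `kind`, `corrected` (substrate x
#'   timepoint matrix) and `times` (hours).
#' @export
correct_od <- function(plate, scheme = substrate_scheme(plate$kind)) {
  if (!identical(scheme$kind[1], plate$kind))
    stop("scheme is for plate kind ", scheme$kind[1], ", not ", plate$kind)
  ctrl_wells <- scheme$well[scheme$group == "control"]
  ctrl_wells <- intersect(ctrl_wells, rownames(plate$od))
  if (length(ctrl_wells) == 0) stop("no control wells present in the plate")
  ctrl <- colMeans(plate$od[ctrl_wells, , drop = FALSE])
  subs <- scheme[scheme$group != "control", ]
  substrates <- unique(subs$substrate)
  corrected <- t(vapply(substrates, function(s) {
    wells <- intersect(subs$well[subs$substrate == s], rownames(plate$od))
    if (length(wells) == 0) stop("substrate has no wells in the plate: ", s)
    colMeans(plate$od[wells, , drop = FALSE]) - ctrl
  }, numeric(ncol(plate$od))))
  corrected[corrected < 0] <- 0
  structure(list(kind = plate$kind, corrected = corrected, times = plate$times),
            class = "plate_profile")
}

# pull the corrected column at one timepoint, with a helpful error
profile_at <- function(profile, time) {
  j <- match(time, profile$times)
  if (is.na(j))
    stop("timepoint ", time, " h not read; available: ",
         paste(profile$times, collapse = ", "))
  profile$corrected[, j]
}

#' Average well colour development (AWCD)
#'
#' Mean control-corrected absorbance over the plate's substrates at one
#' reading time; the standard proxy for community carbon-metabolic activity.
#'
#' @param profile a `plate_profile` from [correct_od()].
#' @param time reading time in hours (default 168).
#' @return AWCD (dimensionless OD).
#' @export
awcd <- function(profile, time = 168) {
  mean(profile_at(profile, time))
}

#' Mean corrected absorbance per substrate group
#'
#' @param profile a `plate_profile`.
#' @param scheme matching [substrate_scheme()].
#' @param time reading time in hours.
#' @return named numeric vector, one mean corrected OD per biochemical group.
#' @export
substrate_group_intensity <- function(profile, scheme = substrate_scheme(profile$kind),
                                      time = 168) {
  if (!identical(scheme$kind[1], profile$kind))
    stop("scheme is for plate kind ", scheme$kind[1], ", not ", profile$kind)
  v <- profile_at(profile, time)
  subs <- unique(scheme[scheme$group != "control", c("substrate", "group")])
  grp <- stats::setNames(subs$group, subs$substrate)[names(v)]
  tapply(v, grp, mean)[unique(subs$group)]
}

#' Functional diversity indices of a plate profile
#'
#' With \eqn{p_i} the proportion of total corrected OD in substrate i:
#' Shannon-Wiener \eqn{H' = -\sum p_i \ln p_i}, Simpson
#' \eqn{D = 1 - \sum p_i^2}, and McIntosh \eqn{U = \sqrt{\sum c_i^2}} on the
#' corrected ODs themselves.
#'
#' @param profile a `plate_profile`.
#' @param time reading time in hours (default 168).
#' @return named numeric vector `c(H, D, U)`.
#' @export
functional_diversity <- function(profile, time = 168) {
  v <- profile_at(profile, time)
  if (all(v == 0)) stop("all corrected values zero: diversity undefined")
  p <- v[v > 0] / sum(v)
  c(H = -sum(p * log(p)), D = 1 - sum(p^2), U = sqrt(sum(v^2)))
}

#' Filter genes by amplification efficiency
#'
#' Genes whose amplification efficiency falls outside the accepted window
#' (default 1.8-2.2, i.e. 80-120% per-cycle doubling) are eliminated.
#'
#' @param efficiency named numeric vector of per-gene efficiencies.
#' @param range length-2 accepted window (default `c(1.8, 2.2)`).
#' @return character vector of retained gene names; removals are messaged.
#' @export
efficiency_filter <- function(efficiency, range = c(1.8, 2.2)) {
  if (any(efficiency <= 0)) stop("efficiencies must be > 0")
  keep <- efficiency >= range[1] & efficiency <= range[2]
  if (any(!keep))
    message("eliminated ", sum(!keep), " gene(s) with efficiency outside [",
            range[1], ", ", range[2], "]: ",
            paste(names(efficiency)[!keep], collapse = ", "))
  names(efficiency)[keep]
}

#' Quantify functional genes from threshold cycles
#'
#' Converts CT values to relative copy numbers with the chip's detection
#' limit at CT = 31: non-detected or at/above-limit reactions score 0,
#' otherwise \eqn{copies = 10^{(31 - CT) \cdot 3/10}} (a perfectly efficient
#' reaction gains one log10 of template every 10/3 cycles).
#'
#' @param genes a `gene_ct` from [read_gene_ct()], or a gene x sample CT
#'   matrix (NA = non-detected).
#' @param detection_ct detection-limit cycle (default 31).
#' @param scale optional per-sample scaling factor (e.g. 16S copy density)
#'   applied multiplicatively for absolute abundances.
#' @return a `gene_abundance`: list with `copies` (gene x sample), `cycle`
#'   (categories, `"unknown"` when not supplied) and `detection_ct`.
#' @export
qmec_quantify <- function(genes, detection_ct = 31, scale = NULL) {
  ct <- if (inherits(genes, "gene_ct")) genes$ct else as.matrix(genes)
  cycle <- if (inherits(genes, "gene_ct")) genes$cycle else
    stats::setNames(rep("unknown", nrow(ct)), rownames(ct))
  copies <- 10^((detection_ct - ct) * 3 / 10)
  copies[is.na(ct) | ct >= detection_ct] <- 0
  if (!is.null(scale)) {
    if (length(scale) != ncol(ct)) stop("scale must have one value per sample")
    copies <- sweep(copies, 2, scale, "*")
  }
  structure(list(copies = copies, cycle = cycle, detection_ct = detection_ct),
            class = "gene_abundance")
}

#' Per-cycle gene-abundance summaries and group comparisons
#'
#' @param abund a `gene_abundance` from [qmec_quantify()].
#' @param groups optional factor of treatment levels, one per sample; when
#'   given, [group_compare()] letters are computed per cycle category.
#' @return list with `per_sample_total`, `per_category` (category x sample
#'   sums, conserving the grand total), and `group_letters` (data.frame, or
#'   NULL without groups).
#' @export
cycle_summaries <- function(abund, groups = NULL) {
  copies <- abund$copies
  total <- colSums(copies)
  cats <- sort(unique(abund$cycle))
  per_cat <- t(vapply(cats, function(cc)
    colSums(copies[abund$cycle == cc, , drop = FALSE]), numeric(ncol(copies))))
  rownames(per_cat) <- cats
  letters_df <- NULL
  if (!is.null(groups)) {
    letters_df <- do.call(rbind, lapply(cats, function(cc) {
      gc <- group_compare(per_cat[cc, ], groups)
      cbind(category = cc, gc, anova_p = attr(gc, "anova_p"))
    }))
  }
  list(per_sample_total = total, per_category = per_cat,
       group_letters = letters_df)
}
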