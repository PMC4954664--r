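# Diet and zooplankton-community statistics: composition tables, the
# linear food selection index with parametric bootstrap, net-haul
# densities, summary t-tests, Calanus size classification, Bray-Curtis /
# Ward community clustering and per-habitat density comparisons.

#' Composition table: relative abundance and occurrence frequency
#'
#' Per sample, relative abundance (RA) of a taxon is its count over the
#' sample total; per group the mean and SD of RA over samples are
#' reported together with the occurrence frequency (OF, percentage of
#' samples in which the taxon occurs). Samples with zero total are
#' excluded with a warning.
#'
#' @param samples long data.frame with `sample_id`, `taxon`, `count` and
#'   the grouping columns.
#' @param group_by character vector of grouping column names (e.g.
#'   `c("source", "year")` or `"stratum"`).
#' @return data.frame: grouping columns, `taxon`, `ra_mean`, `ra_sd`,
#'   `of` (all in %), `n_samples`.
#' @export
composition_table <- function(samples, group_by) {
  stopifnot(all(c("sample_id", "taxon", "count") %in% names(samples)))
  totals <- tapply(samples$count, samples$sample_id, sum)
  empty <- names(totals)[totals == 0]
  if (length(empty)) {
    warning("excluding ", length(empty), " sample(s) with zero total: ",
            paste(head(empty, 5), collapse = ", "))
    samples <- samples[!samples$sample_id %in% empty, , drop = FALSE]
  }
  if (!nrow(samples)) stop("no non-empty samples")
  key <- interaction(samples[group_by], drop = TRUE, sep = "\r")
  out <- lapply(split(samples, key), function(g) {
    taxa <- sort(unique(g$taxon))
    ids <- unique(g$sample_id)
    # sample x taxon RA matrix (missing taxon rows are zero counts)
    m <- matrix(0, length(ids), length(taxa),
                dimnames = list(ids, taxa))
    m[cbind(match(g$sample_id, ids), match(g$taxon, taxa))] <- g$count
    ra <- 100 * m / rowSums(m)
    res <- data.frame(
      taxon = taxa,
      ra_mean = colMeans(ra),
      ra_sd = apply(ra, 2, sd),
      of = 100 * colMeans(m > 0),
      n_samples = length(ids)
    )
    for (col in rev(group_by)) res <- cbind(setNames(
      data.frame(rep(g[[col]][1], nrow(res))), col), res)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Linear food selection index with parametric bootstrap
#'
#' LFSI = GP - E: the difference between a prey taxon's relative
#' abundance in the diet (gular pouch) and in the environment, in [-1, 1];
#' positive values indicate preference. Uncertainty comes from a
#' parametric bootstrap: `n_boot` draws GP* ~ N(gp_mean, gp_sd) and
#' E* ~ N(env_mean, env_sd) independently (not truncated to [0, 1]),
#' reporting their difference's mean, SD and percentile interval.
#'
#' @param gp_mean,gp_sd diet relative abundance, proportion in [0, 1],
#'   and its SD.
#' @param env_mean,env_sd environmental relative abundance and SD.
#' @param n_boot bootstrap draws (>= 100).
#' @param alpha 1 - confidence level for the percentile interval.
#' @param seed integer seed for reproducible draws; `NULL` uses the
#'   current RNG state.
#' @return one-row data.frame: `gp_mean`, `env_mean`, `point`,
#'   `boot_mean`, `boot_sd`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
lfsi <- function(gp_mean, gp_sd, env_mean, env_sd,
                 n_boot = 10000, alpha = 0.05, seed = NULL) {
  stopifnot(gp_mean >= 0, gp_mean <= 1, env_mean >= 0, env_mean <= 1,
            gp_sd >= 0, env_sd >= 0)
  if (n_boot < 100) stop("n_boot must be >= 100")
  draw <- function() {
    gp_star <- rnorm(n_boot, gp_mean, gp_sd)
    e_star <- rnorm(n_boot, env_mean, env_sd)
    gp_star - e_star
  }
  boot <- if (is.null(seed)) draw() else
    withr::with_seed(as.integer(seed), draw())
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  data.frame(gp_mean = gp_mean, env_mean = env_mean,
             point = gp_mean - env_mean,
             boot_mean = mean(boot), boot_sd = sd(boot),
             ci_low = ci[1], ci_high = ci[2],
             n_boot = n_boot,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Selection indices for every taxon of a composition summary
#'
#' Convenience wrapper applying [lfsi()] per taxon, taking diet and
#' environment means/SDs from two composition summaries on the same taxon
#' universe (percent columns are converted to proportions).
#'
#' @param diet_tab,env_tab data.frames with `taxon`, `ra_mean`, `ra_sd`
#'   in percent (as from [composition_table()] or [diet_summary()]
#'   columns).
#' @inheritParams lfsi
#' @return data.frame, one row per taxon.
#' @export
lfsi_table <- function(diet_tab, env_tab, n_boot = 10000, alpha = 0.05,
                       seed = NULL) {
  taxa <- diet_tab$taxon
  env <- env_tab[match(taxa, env_tab$taxon), , drop = FALSE]
  if (anyNA(env$ra_mean)) stop("environment table missing taxa")
  out <- lapply(seq_along(taxa), function(i) {
    s <- if (is.null(seed)) NULL else as.integer(seed) + i
    cbind(taxon = taxa[i],
          lfsi(diet_tab$ra_mean[i] / 100, diet_tab$ra_sd[i] / 100,
               env$ra_mean[i] / 100, env$ra_sd[i] / 100,
               n_boot = n_boot, alpha = alpha, seed = s))
  })
  do.call(rbind, out)
}

#' Individuals per cubic metre from a vertical net haul
#'
#' Density assuming 100% filtration of the cylinder swept by the net:
#' count / (pi * (diameter/2)^2 * haul depth). Defaults are the standard
#' WP2 net (57 cm diameter) hauled from 50 m to the surface.
#'
#' @param count individuals in the sample.
#' @param haul_depth haul depth, m.
#' @param net_diameter net mouth diameter, m.
#' @return individuals per m3.
#' @export
density_per_m3 <- function(count, haul_depth = 50, net_diameter = 0.57) {
  if (any(haul_depth <= 0) || any(net_diameter <= 0))
    stop("haul_depth and net_diameter must be positive")
  count / (pi * (net_diameter / 2)^2 * haul_depth)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student's t (df = n1 + n2 - 2) from group means, SDs
#' and sizes, two-sided; Welch's unequal-variance form is available via
#' `welch = TRUE`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param welch use the Welch-Satterthwaite form.
#' @return data.frame `t`, `df`, `p`.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) stop("t undefined: both SDs zero and means equal")
    stop("t undefined: both SDs are zero")
  }
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  data.frame(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Load the default (assumed) Calanus prosome-length rules
#'
#' @param path optional path to a rules JSON; defaults to the assumed
#'   rules shipped with the package.
#' @return list of class `calanus_rules`.
#' @export
calanus_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "calanus_size_rules.json",
                        package = "aukforage", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- j$rules
  for (i in seq_len(nrow(rules))) {
    cuts <- unlist(rules$cuts_mm[i])
    if (is.unsorted(cuts, strictly = TRUE))
      stop("cut-points must be strictly increasing for stage ",
           rules$stage[i])
  }
  structure(list(species = j$species, rules = rules, note = j$note),
            class = "calanus_rules")
}

#' Classify Calanus individuals to species by stage-specific length
#'
#' Species are assigned by interval membership of the prosome length in
#' the stage's cut-points; a length exactly on a cut-point goes to the
#' larger species. Individuals of a stage with no rule are returned as
#' `NA` with a warning.
#'
#' @param stage copepodite stage labels (e.g. "CIV", "CV", "CVI").
#' @param prosome_length_mm prosome lengths, mm.
#' @param rules a `calanus_rules` object; default [calanus_rules()].
#' @return character vector of species names.
#' @export
classify_calanus <- function(stage, prosome_length_mm,
                             rules = calanus_rules()) {
  out <- rep(NA_character_, length(stage))
  for (st in unique(stage)) {
    i <- which(rules$rules$stage == st)
    sel <- stage == st
    if (!length(i)) {
      warning("no size rule for stage '", st, "'; left unclassified")
      next
    }
    cuts <- unlist(rules$rules$cuts_mm[i])
    # boundary value -> larger species: left-closed intervals via >=
    idx <- findInterval(prosome_length_mm[sel], cuts, left.open = FALSE) + 1
    out[sel] <- rules$species[idx]
  }
  out
}

#' Bray-Curtis dissimilarity and Ward clustering of samples
#'
#' Builds the sample-by-taxon matrix, computes Bray-Curtis dissimilarity
#' (on counts by default, relative abundances via `scale = "ra"`),
#' clusters with Ward's minimum-variance method and cuts the tree at `k`
#' groups. All-zero samples are excluded. The classic minimum-variance
#' agglomeration on (squared) dissimilarities is `"ward.D2"`; the older
#' variant `"ward.D"` is selectable, and results can differ between the
#' two.
#'
#' @param samples long data.frame (`sample_id`, `taxon`, `count`).
#' @param k number of groups to cut.
#' @param scale `"count"` or `"ra"`.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return list: `dist` (dist object), `tree` (hclust), `groups` (named
#'   integer vector), `matrix` (sample x taxon).
#' @export
bray_curtis_ward <- function(samples, k = 2, scale = c("count", "ra"),
                             method = c("ward.D2", "ward.D")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  ids <- unique(samples$sample_id)
  taxa <- sort(unique(samples$taxon))
  if (length(ids) < 2) stop("need at least 2 samples")
  m <- matrix(0, length(ids), length(taxa), dimnames = list(ids, taxa))
  m[cbind(match(samples$sample_id, ids), match(samples$taxon, taxa))] <-
    samples$count
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning("excluding all-zero sample(s): ",
            paste(ids[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  if (scale == "ra") m <- m / rowSums(m)
  d <- vegan::vegdist(m, method = "bray")
  tree <- hclust(d, method = method)
  groups <- cutree(tree, k = k)
  list(dist = d, tree = tree, groups = groups, matrix = m)
}

# compact letter display by insert-and-absorb on a logical
# "significantly different" matrix
.letters_cld <- function(diff_mat) {
  g <- nrow(diff_mat)
  sets <- list(seq_len(g)) # start: everyone shares one letter
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (!diff_mat[i, j]) next
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        a <- setdiff(sets[[s]], i)
        b <- setdiff(sets[[s]], j)
        sets[[s]] <- a
        sets[[length(sets) + 1]] <- b
      }
    }
    # absorb duplicates / subsets
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) for (r in seq_along(sets))
      if (s != r && keep[r] && keep[s] && all(sets[[s]] %in% sets[[r]]) &&
          length(sets[[s]]) < length(sets[[r]])) keep[s] <- FALSE
    sets <- sets[keep]
  }
  lab <- rep("", g)
  for (s in seq_along(sets))
    for (m in sets[[s]]) lab[m] <- paste0(lab[m], letters[s])
  lab
}

#' Compare per-habitat densities: Kruskal-Wallis plus pairwise Wilcoxon
#'
#' Kruskal-Wallis rank-sum test (tie-corrected) across strata, followed
#' by pairwise two-sided Wilcoxon rank-sum tests and a compact letter
#' display at `alpha` (strata sharing no letter differ significantly).
#' Strata with fewer than 2 samples are excluded with a warning. When all
#' observations are identical the statistic is reported as H = 0 with
#' p = 1.
#'
#' @param density numeric vector (e.g. individuals per m3).
#' @param stratum factor/character of the same length.
#' @param alpha significance level for the letter display.
#' @param p_adjust p-adjustment method for the pairwise tests (see
#'   [stats::p.adjust()]); `"none"` by default.
#' @return list: `kw` (data.frame `H`, `df`, `p`), `pairwise` (matrix of
#'   p-values), `letters` (named character vector), `alpha`.
#' @export
habitat_density_compare <- function(density, stratum, alpha = 0.01,
                                    p_adjust = "none") {
  stratum <- as.character(stratum)
  n_by <- table(stratum)
  small <- names(n_by)[n_by < 2]
  if (length(small)) {
    warning("excluding strata with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !stratum %in% small
    density <- density[keep]; stratum <- stratum[keep]
  }
  strata <- sort(unique(stratum))
  if (length(strata) < 2) stop("need >= 2 strata with >= 2 samples each")
  if (length(unique(density)) == 1) {
    kw <- data.frame(H = 0, df = length(strata) - 1, p = 1)
    pw <- matrix(1, length(strata), length(strata),
                 dimnames = list(strata, strata))
    return(list(kw = kw,
                pairwise = pw,
                letters = setNames(rep("a", length(strata)), strata),
                alpha = alpha))
  }
  kt <- kruskal.test(density, factor(stratum))
  pw_t <- suppressWarnings(
    pairwise.wilcox.test(density, factor(stratum), p.adjust.method = p_adjust,
                         exact = FALSE))
  pw <- matrix(NA_real_, length(strata), length(strata),
               dimnames = list(strata, strata))
  for (i in rownames(pw_t$p.value)) for (j in colnames(pw_t$p.value))
    if (!is.na(pw_t$p.value[i, j]))
      pw[i, j] <- pw[j, i] <- pw_t$p.value[i, j]
  diag(pw) <- 1
  diff_mat <- pw < alpha
  lab <- .letters_cld(diff_mat)
  list(kw = data.frame(H = unname(kt$statistic),
                       df = unname(kt$parameter), p = kt$p.value),
       pairwise = pw,
       letters = setNames(lab, strata),
       alpha = alpha)
}
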