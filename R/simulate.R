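# Synthetic CyTOF-like cohorts with known ground truth.
#
# Cells are drawn from a shared Gaussian mixture on the asinh scale
# (diagonal covariance); per-sample population counts follow a multinomial
# whose frequencies carry cohort/week log-fold effects; stimulation shifts
# functional markers in responding populations; and a monotone HAZ
# association can be planted in selected functional markers.

#' Specify one cell population for simulation
#'
#' @param name population name.
#' @param mean named numeric vector of marker means (asinh scale).
#' @param sd per-marker spreads (> 0), recycled from a scalar.
#' @param freq baseline mixture frequency (relative weight, > 0).
#' @param abundance_logfc named numeric vector of log2 fold-changes applied
#'   to the frequency, keyed as \code{"<location>"} or
#'   \code{"<location>.week<week>"}.
#' @param stim_shift named numeric vector of additive shifts applied to
#'   functional markers under stimulation.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(name, mean, sd = 0.35, freq = 1,
                            abundance_logfc = numeric(),
                            stim_shift = numeric()) {
  if (is.null(names(mean))) stop("mean must be a named marker vector")
  if (length(sd) == 1L) sd <- rep(sd, length(mean))
  if (any(sd <= 0)) stop("spreads must be > 0")
  if (freq <= 0) stop("freq must be > 0")
  structure(list(name = name, mean = mean,
                 sd = stats::setNames(sd, names(mean)),
                 freq = freq, abundance_logfc = abundance_logfc,
                 stim_shift = stim_shift),
            class = "population_spec")
}

#' Default 23-marker phenotyping panel and 8-population mixture
#'
#' A compact emulation of a pediatric PBMC phenotyping panel: 23 phenotype
#' markers plus, when \code{stimulated}, 9 functional markers (32 total).
#' Populations: naive/memory CD4 T, naive/effector CD8 T, gamma-delta T, B
#' cells, NK cells and monocytes, with well-separated lineage markers.
#'
#' @param separation scale factor on the population mean separation (default
#'   1; the default means are >= 4 spread units apart on lineage markers).
#' @param stimulated include functional markers and stimulation shifts.
#' @return List with \code{panel} (a \code{marker_panel}) and \code{pops}
#'   (list of \code{population_spec}s).
#' @export
default_mixture <- function(separation = 1, stimulated = FALSE) {
  pheno <- c("CD45", "CD3", "CD4", "CD8a", "CD19", "CD20", "CD56", "TCRgd",
             "CD14", "CD16", "CD45RA", "CD45RO", "CCR7", "CD27", "CD57",
             "CD28", "PD-1", "CD127", "CD25", "HLA-DR", "CD38", "CD161",
             "CD11c")
  func <- c("IL-8", "TGFb", "IL-2", "TNF", "IFNg", "GranzymeB", "Perforin",
            "MIP-1b", "CD40L")
  markers <- if (stimulated) c(pheno, func) else pheno
  base <- stats::setNames(rep(0.3, length(markers)), markers)
  hi <- 3.2 * separation
  mid <- 1.8 * separation
  mk <- function(...) {
    m <- base
    v <- list(...)
    m[names(v)] <- unlist(v) * separation
    m
  }
  shift9 <- function(...) {
    s <- stats::setNames(numeric(length(func)), func)
    v <- list(...)
    s[names(v)] <- unlist(v)
    if (stimulated) s else numeric()
  }
  pops <- list(
    population_spec("CD4T_naive",
      mk(CD45 = hi, CD3 = hi, CD4 = hi, CD45RA = hi, CCR7 = hi, CD27 = hi,
         CD28 = hi, CD127 = mid),
      freq = 0.24, abundance_logfc = c(Bangladesh = -0.3),
      stim_shift = shift9(`IL-2` = 1.2, `IL-8` = 1.0, CD40L = 1.4)),
    population_spec("CD4T_memory",
      mk(CD45 = hi, CD3 = hi, CD4 = hi, CD45RO = hi, CD27 = mid, CD28 = hi,
         CD127 = mid, CD25 = mid),
      freq = 0.16,
      stim_shift = shift9(`IL-2` = 1.6, TNF = 1.4, IFNg = 1.0, TGFb = 0.8,
                          CD40L = 1.2)),
    population_spec("CD8T_naive",
      mk(CD45 = hi, CD3 = hi, CD8a = hi, CD45RA = hi, CCR7 = hi, CD27 = hi,
         CD28 = mid),
      freq = 0.15, abundance_logfc = c(Bangladesh.week104 = -0.4,
                                       Bangladesh.week156 = -0.4)),
    population_spec("CD8T_effector",
      mk(CD45 = hi, CD3 = hi, CD8a = hi, CD45RA = mid, CD57 = hi,
         CD38 = mid),
      freq = 0.08, abundance_logfc = c(Bangladesh.week104 = 0.6,
                                       Bangladesh.week156 = 0.7),
      stim_shift = shift9(IFNg = 1.6, TNF = 1.2, GranzymeB = 1.8,
                          Perforin = 1.6, `MIP-1b` = 1.2)),
    population_spec("gdT",
      mk(CD45 = hi, CD3 = hi, TCRgd = hi, CD161 = mid),
      freq = 0.05,
      stim_shift = shift9(IFNg = 1.2, TNF = 1.0, `IL-8` = 0.6, TGFb = 0.6)),
    population_spec("Bcells",
      mk(CD45 = hi, CD19 = hi, CD20 = hi, `HLA-DR` = hi),
      freq = 0.14, abundance_logfc = c(Bangladesh.week104 = 0.45),
      stim_shift = shift9(`IL-8` = 0.8)),
    population_spec("NK",
      mk(CD45 = hi, CD56 = hi, CD16 = hi, CD57 = mid),
      freq = 0.10,
      stim_shift = shift9(GranzymeB = 1.6, Perforin = 1.4, `MIP-1b` = 1.0,
                          `IL-8` = 0.5)),
    population_spec("Monocytes",
      mk(CD45 = hi, CD14 = hi, CD11c = hi, `HLA-DR` = hi, CD16 = mid),
      freq = 0.08, abundance_logfc = c(Bangladesh.week104 = -0.6,
                                       Bangladesh.week156 = -0.6),
      stim_shift = shift9(`IL-8` = 1.0, TNF = 1.2)))
  panel <- marker_panel(markers,
                        weights = 1,
                        roles = c(rep("phenotype", length(pheno)),
                                  rep("function", length(markers) -
                                        length(pheno))))
  list(panel = panel, pops = pops)
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the study design this generator emulates: Bangladeshi and
#' American children sampled at weeks 53/104/156, stimulated and unstimulated
#' conditions, HAZ drawn for Bangladeshi donors from a normal centred at
#' -1.5 (SD 1), truncated to [-4, 1].
#'
#' @param n_donors named list: donors per location, e.g.
#'   \code{list(Bangladesh = 8, USA = 5)}.
#' @param weeks timepoints sampled (default 53).
#' @param conditions \code{"unstim"}, \code{"stim"} or both.
#' @param haz_mean,haz_sd HAZ distribution for Bangladeshi donors.
#' @param planted data frame of planted HAZ associations (columns
#'   \code{population}, \code{marker}, \code{effect_sd}) or \code{NULL}.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_donors = list(Bangladesh = 8, USA = 5),
                        weeks = 53, conditions = c("unstim", "stim"),
                        haz_mean = -1.5, haz_sd = 1,
                        planted = NULL) {
  stopifnot(all(unlist(n_donors) >= 1))
  if (!all(conditions %in% c("unstim", "stim")))
    stop("conditions must be 'unstim' and/or 'stim'")
  structure(list(n_donors = n_donors, weeks = weeks,
                 conditions = conditions, haz_mean = haz_mean,
                 haz_sd = haz_sd, planted = planted),
            class = "cohort_spec")
}

#' Simulate a CyTOF-like cohort with known ground truth
#'
#' Per sample, population counts are drawn from a multinomial with
#' effect-adjusted frequencies and cell marker values from each population's
#' diagonal Gaussian on the asinh scale; stimulation adds the populations'
#' functional shifts plus donor-level noise. Returns the tables, full
#' metadata and true per-cell population labels.
#'
#' @param spec a \code{cohort_spec}.
#' @param mixture output of \code{\link{default_mixture}} (or a compatible
#'   list with \code{panel} and \code{pops}).
#' @param cells_per_sample cells drawn per sample (default 6000).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   it.
#' @return List with \code{tables} (list of transformed \code{cell_table}s),
#'   \code{meta} (one row per sample), \code{truth} (list of integer
#'   population labels per sample) and \code{pop_names}.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            mixture = default_mixture(
                              stimulated = "stim" %in% spec$conditions),
                            cells_per_sample = 6000, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  pops <- mixture$pops
  panel <- mixture$panel
  npop <- length(pops)
  with_seed(seed, {
    tables <- list(); truth <- list(); meta <- list()
    si <- 0L
    for (loc in names(spec$n_donors)) {
      for (d in seq_len(spec$n_donors[[loc]])) {
        donor <- sprintf("%s_d%02d", loc, d)
        haz <- if (loc == "Bangladesh")
          max(-4, min(1, stats::rnorm(1, spec$haz_mean, spec$haz_sd)))
        else NA_real_
        sexes <- c("F", "M")
        sex <- sample(sexes, 1)
        cmv <- sample(c("pos", "neg"), 1,
                      prob = if (loc == "Bangladesh") c(0.8, 0.2)
                             else c(0.2, 0.8))
        eth <- if (loc == "Bangladesh") "Bengali"
               else sample(c("White", "Hispanic", "Asian"), 1)
        donor_noise <- stats::rnorm(npop, 0, 0.15)
        for (wk in spec$weeks) {
          for (cond in spec$conditions) {
            si <- si + 1L
            sid <- sprintf("%s_w%d_%s", donor, wk, cond)
            lf <- vapply(pops, function(p) {
              key_w <- paste0(loc, ".week", wk)
              sum(p$abundance_logfc[c(loc, key_w)], na.rm = TRUE)
            }, numeric(1))
            freqs <- vapply(pops, `[[`, numeric(1), "freq") *
              2^(lf + donor_noise)
            freqs <- freqs / sum(freqs)
            counts <- as.vector(stats::rmultinom(1, cells_per_sample, freqs))
            lab <- rep(seq_len(npop), counts)
            vals <- matrix(0, length(lab), length(panel$markers),
                           dimnames = list(NULL, panel$markers))
            row0 <- 0L
            for (pi in seq_len(npop)) {
              if (!counts[pi]) next
              p <- pops[[pi]]
              mu <- p$mean[panel$markers]
              if (cond == "stim" && length(p$stim_shift))
                mu[names(p$stim_shift)] <- mu[names(p$stim_shift)] +
                  p$stim_shift
              block <- matrix(stats::rnorm(counts[pi] * length(mu),
                                           mean = rep(mu, each = counts[pi]),
                                           sd = rep(p$sd[panel$markers],
                                                    each = counts[pi])),
                              nrow = counts[pi])
              vals[row0 + seq_len(counts[pi]), ] <- block
              row0 <- row0 + counts[pi]
            }
            tables[[sid]] <- cell_table(vals, sid, transformed = TRUE)
            truth[[sid]] <- lab
            meta[[sid]] <- data.frame(
              sample_id = sid, donor_id = donor, location = loc,
              week = wk, condition = cond, sex = sex, ethnicity = eth,
              cmv_status = cmv, haz = haz,
              batch_set = paste0("set", 1L + (si - 1L) %% 3L),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    sim <- list(tables = tables, meta = do.call(rbind, meta),
                truth = truth,
                pop_names = vapply(pops, `[[`, character(1), "name"),
                panel = panel, pops = pops)
    rownames(sim$meta) <- NULL
    if (!is.null(spec$planted))
      sim <- plant_haz_effect(sim, spec$planted)
    sim
  })
}

#' Plant a HAZ association into stimulated samples
#'
#' For each (population, marker) row of \code{planted}, the marker values of
#' that population's cells are shifted upward by \code{effect_sd} population
#' SD units in the stimulated samples of more-stunted Bangladeshi donors
#' (HAZ <= threshold) and of American donors, emulating a U-shaped
#' association in which the non-stunted Bangladeshi group sits lowest.
#' Unstimulated samples are untouched.
#'
#' @param sim output of \code{\link{simulate_cohort}}.
#' @param planted data frame with columns \code{population}, \code{marker},
#'   \code{effect_sd}.
#' @param haz_threshold stunting cut-off (default -1.5).
#' @return The modified simulation object.
#' @export
plant_haz_effect <- function(sim, planted, haz_threshold = -1.5) {
  stopifnot(is.data.frame(planted),
            all(c("population", "marker", "effect_sd") %in% names(planted)))
  meta <- sim$meta
  target <- meta$condition == "stim" &
    ((meta$location == "Bangladesh" & !is.na(meta$haz) &
        meta$haz <= haz_threshold) | meta$location == "USA")
  for (r in seq_len(nrow(planted))) {
    pop <- planted$population[r]
    mk <- planted$marker[r]
    pi <- match(pop, sim$pop_names)
    if (is.na(pi)) stop("unknown population: ", pop)
    shift <- planted$effect_sd[r] * unname(sim$pops[[pi]]$sd[mk])
    for (sid in meta$sample_id[target]) {
      tab <- sim$tables[[sid]]
      if (!mk %in% colnames(tab$values)) stop("unknown marker: ", mk)
      rows <- sim$truth[[sid]] == pi
      tab$values[rows, mk] <- tab$values[rows, mk] + shift
      sim$tables[[sid]] <- tab
    }
  }
  sim
}

#' Per-sample functional features: positive fractions per population x marker
#'
#' The screened feature for population P and marker M in a sample is the
#' fraction of the sample's P cells whose (asinh) value of M exceeds
#' \code{threshold} - a "frequency of marker-positive cells" as produced by
#' gating.
#'
#' @param sim a simulation object (\code{\link{simulate_cohort}}), or a list
#'   with \code{tables} and \code{truth} using the same layout.
#' @param markers functional markers to tabulate.
#' @param condition which samples to include (default \code{"stim"}).
#' @param threshold positivity threshold on the asinh scale (default 1).
#' @return samples x (population.marker) matrix of fractions.
#' @export
functional_features <- function(sim, markers, condition = "stim",
                                threshold = 1) {
  ids <- sim$meta$sample_id[sim$meta$condition == condition]
  npop <- length(sim$pop_names)
  feats <- lapply(ids, function(sid) {
    tab <- sim$tables[[sid]]
    lab <- sim$truth[[sid]]
    unlist(lapply(seq_len(npop), function(pi) {
      rows <- lab == pi
      vapply(markers, function(mk) {
        if (!any(rows)) return(NA_real_)
        mean(tab$values[rows, mk] > threshold)
      }, numeric(1))
    }))
  })
  out <- do.call(rbind, feats)
  colnames(out) <- as.vector(t(outer(sim$pop_names, markers, paste,
                                     sep = ".")))
  rownames(out) <- ids
  out
}

#' Simulate a feature-level screening cohort
#'
#' Generates the sample x feature table the HAZ screen consumes directly:
#' independent unit-variance Gaussian features for five American (group 0),
#' eight less-stunted and eight more-stunted Bangladeshi samples (the study's
#' screening layout), with an optional planted elevation in groups 0 and 2 by
#' \code{effect_sd} SD units - the U-shaped pattern the event criterion is
#' designed to detect. A functional marker is measured once per cell
#' population, so a real association surfaces as several correlated features;
#' the elevation is therefore planted in \code{n_planted} features sharing
#' the same signal (default 4, mirroring a cytokine seen across four
#' populations).
#'
#' @param n0,n1,n2 group sizes (defaults 5, 8, 8).
#' @param n_features number of features (default 40).
#' @param effect_sd planted elevation in SD units (0 = null cohort).
#' @param n_planted number of correlated features carrying the elevation.
#' @param seed integer seed.
#' @return List with \code{features} (matrix), \code{meta} (with
#'   \code{location} and \code{haz}), \code{planted_feature} (first planted
#'   name or \code{NA}) and \code{planted_features}.
#' @export
simulate_feature_cohort <- function(n0 = 5, n1 = 8, n2 = 8, n_features = 40,
                                    effect_sd = 0, n_planted = 4,
                                    seed = 1L) {
  with_seed(seed, {
    n <- n0 + n1 + n2
    ids <- sprintf("s%02d", seq_len(n))
    meta <- data.frame(
      sample_id = ids,
      location = rep(c("USA", "Bangladesh"), c(n0, n1 + n2)),
      haz = c(rep(NA_real_, n0), stats::runif(n1, -1.4, 0.5),
              stats::runif(n2, -3, -1.6)),
      stringsAsFactors = FALSE)
    feats <- matrix(stats::rnorm(n * n_features), n, n_features,
                    dimnames = list(ids, paste0("feat", seq_len(n_features))))
    planted <- character(0)
    if (effect_sd != 0) {
      planted <- colnames(feats)[seq_len(min(n_planted, n_features))]
      in02 <- c(rep(TRUE, n0), rep(FALSE, n1), rep(TRUE, n2))
      feats[in02, planted] <- feats[in02, planted] + effect_sd
    }
    list(features = feats, meta = meta,
         planted_feature = if (length(planted)) planted[1] else NA_character_,
         planted_features = planted)
  })
}

#' Hand-specified bin graph fixture
#'
#' Builds a \code{bin_graph} directly from axial coordinates, expression
#' vectors and per-bin cell counts, with border adjacency (and nearest
#' fallback) derived exactly as for real grids - the oracle fixture for
#' clustering tests.
#'
#' @param q,r integer axial coordinates per bin.
#' @param expression bins x markers matrix (default: the centers themselves).
#' @param counts cells per bin (default 1).
#' @param hex_radius hexagon radius (default 1).
#' @return A \code{bin_graph} with adjacency edges.
#' @export
make_fixture_bingraph <- function(q, r, expression = NULL, counts = 1,
                                  hex_radius = 1) {
  stopifnot(length(q) == length(r))
  n <- length(q)
  if (n > 200) stop("fixture graphs are capped at 200 bins")
  o <- order(q, r)
  q <- as.integer(q)[o]; r <- as.integer(r)[o]
  cx <- 1.5 * hex_radius * q
  cy <- sqrt(3) * hex_radius * (r + q / 2)
  if (is.null(expression)) expression <- cbind(x = cx, y = cy)
  else expression <- as.matrix(expression)[o, , drop = FALSE]
  if (is.null(colnames(expression)))
    colnames(expression) <- paste0("m", seq_len(ncol(expression)))
  if (length(counts) == 1L) counts <- rep(counts, n)
  counts <- as.integer(counts)[o]
  g <- structure(list(
    bins = data.frame(bin_id = seq_len(n), q = q, r = r, cx = cx, cy = cy,
                      n_cells = counts),
    expression = expression,
    cell_bin = rep(seq_len(n), counts),
    sample_id = rep("fixture", sum(counts)),
    hex_radius = hex_radius,
    edges = data.frame(a = integer(), b = integer(), kind = character())),
    class = "bin_graph")
  build_adjacency(g)
}
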