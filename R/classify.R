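# Cell-type classification: a two-feature logistic model separating
# excitatory from inhibitory cells (dendritic spine density vs dendritic
# shaft-synapse density), axon-stem identification, and heuristic
# compartment labelling including the axon initial segment.

#' Fit the excitatory/inhibitory logistic model
#'
#' Maximum-likelihood logistic regression of cell class on two spine/synapse
#' features (dendritic spine density and dendritic shaft-synapse density,
#' both per um).  Probabilities increase toward `"inhibitory"` with
#' shaft-synapse density and decrease with spine density.
#'
#' @param data tibble with the feature columns and a `cell_class` column
#'   (`"excitatory"`/`"inhibitory"`).
#' @param features character vector naming the two feature columns.
#' @return an object of class `ei_model` wrapping the `glm` fit.
#' @export
fit_ei <- function(data,
                   features = c("spine_density_um", "shaft_density_um")) {
  if (!all(features %in% names(data)))
    stop("missing feature columns: ",
         paste(setdiff(features, names(data)), collapse = ", "))
  y <- factor(data$cell_class, levels = c("excitatory", "inhibitory"))
  if (length(unique(stats::na.omit(y))) < 2)
    stop("fit_ei needs examples of both classes")
  df <- data.frame(.y = y, data[, features, drop = FALSE])
  fml <- stats::as.formula(paste(".y ~", paste(features, collapse = " + ")))
  fit <- stats::glm(fml, data = df, family = stats::binomial())
  structure(list(fit = fit, features = features, threshold = 0.5),
            class = "ei_model")
}

#' @export
print.ei_model <- function(x, ...) {
  co <- stats::coef(x$fit)
  cat("<ei_model> logit P(inhibitory) =",
      paste(sprintf("%+.3f", co),
            c("(intercept)", x$features), collapse = " "), "\n")
  invisible(x)
}

#' Predict cell classes from an E/I model
#'
#' @param object an `ei_model`.
#' @param newdata tibble with the model's feature columns.
#' @param ... unused.
#' @return tibble with `p_inhibitory` and `cell_class_pred`.
#' @export
predict.ei_model <- function(object, newdata, ...) {
  p <- stats::predict(object$fit, newdata = as.data.frame(newdata),
                      type = "response")
  tibble::tibble(
    p_inhibitory = as.numeric(p),
    cell_class_pred = ifelse(p >= object$threshold, "inhibitory",
                             "excitatory"))
}

#' Broom-style tidiers for the E/I model
#'
#' @param x an `ei_model`.
#' @param ... unused.
#' @return `tidy()`: one row per coefficient; `glance()`: one-row model
#'   summary.
#' @method tidy ei_model
#' @export
tidy.ei_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3],
                 p_value = s[, 4])
}

#' @rdname tidy.ei_model
#' @method glance ei_model
#' @export
glance.ei_model <- function(x, ...) {
  tibble::tibble(null_deviance = x$fit$null.deviance,
                 deviance = x$fit$deviance,
                 aic = x$fit$aic, nobs = stats::nobs(x$fit))
}

#' The two E/I features of one neuron
#'
#' Dendritic spine density and dendritic shaft-synapse density per um,
#' computed over the non-axonal branches of a decomposition graph.
#'
#' @param graph a `neuro_decomp` with spines detected and synapses labelled.
#' @return one-row tibble `spine_density_um`, `shaft_density_um`.
#' @export
neuron_ei_features <- function(graph) {
  nf <- node_features(graph)
  dend <- nf[is.na(nf$compartment) |
               !(nf$compartment %in% c("axon", "AIS")), ]
  L_um <- sum(dend$skeletal_length_nm) / 1000
  tibble::tibble(
    spine_density_um = sum(dend$spine_count) / L_um,
    shaft_density_um = sum(dend$shaft_synapse_count) / L_um)
}

#' Identify the axon stem of a decomposition graph
#'
#' Scores every stem by outgoing-synapse fraction (the dominant signal),
#' penalised by spine density and width; the top-scoring stem above the
#' outgoing-fraction floor is the axon.  Ties break toward the lowest stem
#' id.  Returns `NA` when no stem qualifies (e.g. dendrite-only
#' reconstructions).
#'
#' @param graph a `neuro_decomp` with synapse directions.
#' @param min_outgoing_fraction floor on the stem's outgoing fraction
#'   (default 0.5).
#' @param min_synapses minimum synapses on the stem to score it.
#' @return stem branch id or `NA_integer_`.
#' @export
identify_axon <- function(graph, min_outgoing_fraction = 0.5,
                          min_synapses = 3) {
  syn <- graph$synapses
  stems <- decomp_children(graph, 0L)
  best <- NA_integer_; best_score <- -Inf
  for (s in stems) {
    ids <- decomp_descendants(graph, s, include_self = TRUE)
    bs <- graph$branches[ids]
    sids <- unlist(lapply(bs, `[[`, "synapse_ids"))
    if (is.null(syn) || length(sids) < min_synapses) next
    out_frac <- mean(syn$direction[match(sids, syn$synapse_id)] ==
                       "outgoing", na.rm = TRUE)
    if (is.na(out_frac) || out_frac < min_outgoing_fraction) next
    L_um <- sum(vapply(bs, `[[`, 0, "skeletal_length")) / 1000
    spine_d <- sum(vapply(bs, function(b) length(b$spine_ids),
                          integer(1))) / L_um
    width <- stats::weighted.mean(
      vapply(bs, function(b) mean(b$width, na.rm = TRUE), numeric(1)),
      vapply(bs, `[[`, 0, "skeletal_length"))
    score <- out_frac - 0.5 * min(spine_d, 1) - 0.1 * width / 1000
    if (score > best_score + 1e-12) { best_score <- score; best <- s }
  }
  best
}

#' Label neural compartments
#'
#' Heuristic compartment labelling: the identified axon stem is `axon`, with
#' branches whose skeletal walk starts within `ais_window` nm of the soma
#' labelled `AIS`; for excitatory cells the dendritic stem pointing most
#' directly away from `depth_axis` (toward the pia) with the largest initial
#' width becomes `apical` (its offshoots `oblique`), remaining dendritic
#' stems `basal`; inhibitory cells get `basal` dendrites throughout.
#'
#' @param graph a `neuro_decomp`.
#' @param cell_class `"excitatory"` or `"inhibitory"`.
#' @param depth_axis unit 3-vector pointing away from the pia (toward
#'   increasing cortical depth).
#' @param ais_window AIS window along the axon walk, nm (default 50000).
#' @param axon_stem optional explicit axon stem id; computed by
#'   [identify_axon()] when `NULL`.
#' @return the graph with per-branch `compartment` labels and synapse
#'   `compartment` column filled.
#' @export
label_compartments <- function(graph, cell_class = "excitatory",
                               depth_axis = c(0, 0, 1), ais_window = 50000,
                               axon_stem = NULL) {
  if (is.null(axon_stem)) axon_stem <- identify_axon(graph)
  active <- active_branch_ids(graph)
  stems <- decomp_children(graph, 0L)
  for (id in active) graph$branches[[id]]$compartment <- "basal"

  if (!is.na(axon_stem)) {
    ids <- decomp_descendants(graph, axon_stem, include_self = TRUE)
    # walk distance from soma to each branch start
    walk_start <- function(id) {
      w <- 0
      while (id != axon_stem) {
        par <- graph$branches[[id]]$parent
        w <- w + graph$branches[[par]]$skeletal_length
        id <- par
      }
      w
    }
    for (id in ids)
      graph$branches[[id]]$compartment <-
        if (walk_start(id) <= ais_window) "AIS" else "axon"
    # AIS only applies from the soma outward: the stem root within the
    # window, descendants once the window is exhausted
  }

  dend_stems <- setdiff(stems, axon_stem)
  if (identical(cell_class, "excitatory") && length(dend_stems) > 0) {
    pia <- -unitize(depth_axis)
    score <- vapply(dend_stems, function(s) {
      b <- graph$branches[[s]]
      dirv <- branch_window_direction(b, "start")
      ca <- sum(dirv * pia)
      if (is.na(ca)) return(-Inf)
      ca + 0.3 * mean(b$width, na.rm = TRUE) /
        max(vapply(dend_stems, function(x)
          mean(graph$branches[[x]]$width, na.rm = TRUE), numeric(1)))
    }, numeric(1))
    if (any(score > 0.3)) {
      ap <- dend_stems[which.max(score)]
      graph$branches[[ap]]$compartment <- "apical"
      for (id in decomp_descendants(graph, ap))
        graph$branches[[id]]$compartment <- "oblique"
    }
  }
  if (!is.null(graph$synapses) && nrow(graph$synapses) > 0) {
    comp <- vapply(graph$branches, `[[`, "", "compartment")
    bid <- graph$synapses$branch_id
    graph$synapses$compartment <- ifelse(
      !is.na(bid) & bid == 0L, "soma",
      ifelse(!is.na(bid), comp[pmax(bid, 1L)], NA_character_))
  }
  graph$cell_class <- cell_class
  graph
}
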