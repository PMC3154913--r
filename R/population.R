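## Population-level inference: pool thinned per-animal posterior-mean beta(t)
## trajectories, cluster them with a full-covariance Gaussian mixture whose
## component count is chosen by BIC, convert assignments to per-animal
## time-budget proportions, and test subgroup differences with a
## classification tree. Clusters are labelled 1..G in order of decreasing
## prevalence, which also breaks label switching.

#' Extract a coefficient trajectory from a fitted model
#'
#' @param fit a `velm` fit.
#' @param animal animal identifier (defaults to the fit's track id).
#' @param group optional subgroup label (sex, year, ...).
#' @return data.frame with columns `animal`, `group`, `time`, then one
#'   posterior-mean column per covariate (plus `<cov>_sd` spread columns).
#' @export
beta_trajectory <- function(fit, animal = NULL, group = NA_character_) {
  stopifnot(inherits(fit, "velm"))
  if (is.null(animal)) animal <- if (is.na(fit$track_id)) "animal" else fit$track_id
  out <- data.frame(animal = as.character(animal), group = as.character(group),
                    time = fit$times, fit$beta_mean, check.names = FALSE)
  sds <- fit$beta_sd
  colnames(sds) <- paste0(fit$covariates, "_sd")
  cbind(out, sds)
}

#' Pool thinned coefficient trajectories across animals
#'
#' Keeps every `thin`-th time point of each trajectory (thinning tempers the
#' strong temporal autocorrelation of `beta(t)` and keeps the pooled matrix
#' tractable) and concatenates the rows with animal/time provenance.
#'
#' @param trajectories list of [beta_trajectory()] data.frames sharing one
#'   covariate set.
#' @param thin keep every `thin`-th row per trajectory (>= 1).
#' @return data.frame of pooled rows; attribute `covariates` names the
#'   coefficient columns.
#' @export
pool_beta_trajectories <- function(trajectories, thin = 100L) {
  if (thin < 1L) stop("thin must be >= 1")
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  covs <- function(df) setdiff(names(df), c("animal", "group", "time",
                                            grep("_sd$", names(df), value = TRUE)))
  c0 <- covs(trajectories[[1L]])
  rows <- lapply(trajectories, function(df) {
    if (!identical(covs(df), c0))
      stop("trajectories have mismatched covariate sets")
    df[seq(1L, nrow(df), by = thin), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "covariates") <- c0
  out
}

#' Cluster pooled coefficients into population movement regimes
#'
#' Fits full-covariance Gaussian mixtures (mclust family "VVV") by EM for
#' each candidate component count and keeps the BIC-best model. Components
#' are relabelled 1..G in order of decreasing mixing weight.
#'
#' @param pooled output of [pool_beta_trajectories()] (or a plain numeric
#'   matrix of coefficient rows).
#' @param G integer vector of candidate component counts (default 1:8).
#' @param seed RNG seed for the EM initialization.
#' @return object of class `regime_cluster`: mixing weights, mean vectors,
#'   covariances, selected `G`, the BIC trace, and the relabelling.
#' @export
cluster_regimes <- function(pooled, G = 1:8, seed = 1) {
  if (is.data.frame(pooled)) {
    covs <- attr(pooled, "covariates")
    if (is.null(covs)) covs <- setdiff(names(pooled), c("animal", "group", "time"))
    Xm <- as.matrix(pooled[, covs, drop = FALSE])
  } else {
    Xm <- as.matrix(pooled)
    covs <- colnames(Xm)
    if (is.null(covs)) covs <- paste0("b", seq_len(ncol(Xm)))
  }
  if (nrow(Xm) <= max(G) * (ncol(Xm) + 1L))
    stop("too few pooled rows (", nrow(Xm), ") for up to ", max(G), " components")
  if (!is.null(seed)) set.seed(seed)
  ## Mclust resolves helpers in the calling frame, so give it a frame whose
  ## parent is the mclust namespace (works without attaching the package)
  env <- new.env(parent = asNamespace("mclust"))
  env$.X <- Xm; env$.G <- G
  mc <- eval(quote(Mclust(.X, G = .G, modelNames = "VVV", verbose = FALSE)), env)
  if (is.null(mc) || is.null(mc$G)) stop("mixture fitting failed for every candidate G")
  Gsel <- mc$G
  w <- mc$parameters$pro
  ord <- order(w, decreasing = TRUE)
  means <- mc$parameters$mean[, ord, drop = FALSE]
  sigs <- mc$parameters$variance$sigma[, , ord, drop = FALSE]
  structure(list(G = Gsel, weights = w[ord],
                 means = means, covariances = sigs,
                 covariates = covs,
                 bic = mc$BIC[, "VVV"],
                 loglik = mc$loglik, n = nrow(Xm)),
            class = "regime_cluster")
}

#' @export
print.regime_cluster <- function(x, ...) {
  cat("Movement-regime mixture: G =", x$G, "components on", x$n, "pooled points\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

## posterior component probabilities of rows of Xm under the cluster model
regime_posterior <- function(model, Xm) {
  G <- model$G
  p <- nrow(model$means)
  n <- nrow(Xm)
  logd <- matrix(0, n, G)
  for (g in seq_len(G)) {
    U <- chol(model$covariances[, , g])
    z <- backsolve(U, t(Xm) - model$means[, g], transpose = TRUE)
    logd[, g] <- log(model$weights[g]) - colSums(z * z) / 2 -
      sum(log(diag(U))) - p * log(2 * pi) / 2
  }
  mx <- apply(logd, 1L, max)
  pr <- exp(logd - mx)
  pr / rowSums(pr)
}

#' Classify pooled points into regimes
#'
#' Maximum-posterior-probability assignment; exact ties go to the
#' lowest-index (most prevalent) cluster.
#'
#' @param model a [cluster_regimes()] model.
#' @param pooled pooled data.frame or coefficient matrix.
#' @return integer vector of regime labels.
#' @export
regime_assign <- function(model, pooled) {
  Xm <- if (is.data.frame(pooled))
    as.matrix(pooled[, model$covariates, drop = FALSE]) else as.matrix(pooled)
  pr <- regime_posterior(model, Xm)
  apply(pr, 1L, which.max)   # which.max takes the first (lowest) index on ties
}

#' Per-animal regime time-budget proportions
#'
#' Assigns each pooled (thinned) time point to a regime and computes, per
#' animal, the proportion of its at-sea points in each regime; multiple trips
#' of one animal are merged before normalizing, so each row sums to 1.
#'
#' @param pooled pooled trajectory data.frame (with `animal`, `group`).
#' @param model a [cluster_regimes()] model.
#' @return data.frame: `animal`, `group`, then `cluster_1..G` proportions.
#' @export
regime_proportions <- function(pooled, model) {
  lab <- regime_assign(model, pooled)
  animals <- unique(pooled$animal)
  G <- model$G
  out <- matrix(0, length(animals), G,
                dimnames = list(animals, paste0("cluster_", seq_len(G))))
  grp <- character(length(animals))
  for (i in seq_along(animals)) {
    rows <- pooled$animal == animals[i]
    out[i, ] <- tabulate(lab[rows], nbins = G) / sum(rows)
    grp[i] <- pooled$group[rows][1L]
  }
  data.frame(animal = animals, group = grp, out, row.names = NULL)
}

#' Test subgroup differences in regime use with a classification tree
#'
#' Binary recursive partitioning (Gini impurity, minimum leaf size 3, depth
#' at most 3) of the per-animal regime proportions with the subgroup label as
#' the response. Reports the root-split variable, resubstitution accuracy
#' (the headline metric) and a cross-validated accuracy.
#'
#' @param props output of [regime_proportions()].
#' @param label column holding the subgroup label (default `"group"`).
#' @return object of class `subgroup_tree`: the `rpart` fit, `accuracy`,
#'   `cv_accuracy`, `root_variable` (NA when the tree has no split), and the
#'   majority-class rate.
#' @export
subgroup_tree <- function(props, label = "group") {
  y <- factor(props[[label]])
  if (nlevels(y) < 2L) stop("subgroup_tree needs at least 2 classes present")
  if (nrow(props) < 10L) stop("subgroup_tree needs at least 10 animals")
  vars <- grep("^cluster_", names(props), value = TRUE)
  df <- data.frame(.y = y, props[, vars, drop = FALSE])
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(minbucket = 3L, maxdepth = 3L,
                                                     cp = 0.01, xval = 10L))
  pred <- stats::predict(fit, type = "class")
  acc <- mean(pred == y)
  root_var <- if (nrow(fit$frame) > 1L)
    as.character(fit$frame$var[1L]) else NA_character_
  cv_acc <- NA_real_
  cp <- fit$cptable
  if (!is.null(cp) && "xerror" %in% colnames(cp)) {
    base_err <- 1 - max(table(y)) / length(y)
    cv_acc <- 1 - min(cp[, "xerror"]) * base_err
  }
  structure(list(tree = fit, accuracy = acc, cv_accuracy = cv_acc,
                 root_variable = root_var,
                 majority_rate = max(table(y)) / length(y)),
            class = "subgroup_tree")
}

#' @export
print.subgroup_tree <- function(x, ...) {
  cat("Subgroup classification tree\n")
  if (is.na(x$root_variable)) {
    cat("  no informative split (accuracy = majority rate ",
        sprintf("%.2f", x$majority_rate), ")\n", sep = "")
  } else {
    cat("  root split on ", x$root_variable,
        sprintf("; resubstitution accuracy %.2f", x$accuracy),
        sprintf(" (cv %.2f)\n", x$cv_accuracy), sep = "")
    print(x$tree)
  }
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Agreement between two partitions corrected for chance; 1 means identical
#' partitions up to relabelling.
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sc <- function(n) n * (n - 1) / 2
  sum_ij <- sum(sc(tab))
  sum_a <- sum(sc(rowSums(tab)))
  sum_b <- sum(sc(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / sc(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
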