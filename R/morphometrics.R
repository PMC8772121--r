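#' Read landmark configurations from a TPS file
#'
#' Parses the plain-text TPS landmark dialect: an `LM=k` record followed by
#' `k` whitespace-separated coordinate lines, with optional `IMAGE=`, `ID=`
#' and `SCALE=` records per specimen.  `SCALE` is applied multiplicatively;
#' the specimen identifier is taken from `ID=`, else `IMAGE=`, else a running
#' index.
#'
#' @param path path to a TPS file.
#' @return list of configurations, each a list with `id`, `coords`
#'   (k x 2 matrix, scale already applied) and `scale`.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("cannot read TPS file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0) stop("no LM= record found in ", path)
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (s in seq_along(starts)) {
    block <- lines[starts[s]:(bounds[s + 1] - 1L)]
    k <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    coord_lines <- grep("^[-+0-9.]", block[-1], value = TRUE)
    id <- .tps_field(block, "ID")
    if (is.na(id)) id <- .tps_field(block, "IMAGE")
    if (is.na(id)) id <- paste0("specimen_", s)
    if (length(coord_lines) != k)
      stop("TPS specimen ", id, ": LM=", k, " but ",
           length(coord_lines), " coordinate lines")
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"),
                                function(v) as.numeric(v[1:2])))
    if (anyNA(xy)) stop("TPS specimen ", id, ": unparseable coordinates")
    sc <- suppressWarnings(as.numeric(.tps_field(block, "SCALE")))
    if (!is.na(sc)) xy <- xy * sc
    out[[s]] <- list(id = id, coords = xy,
                     scale = if (is.na(sc)) NULL else sc)
  }
  out
}

.tps_field <- function(block, key) {
  m <- grep(paste0("^", key, "\\s*="), block, ignore.case = TRUE, value = TRUE)
  if (length(m) == 0) NA_character_ else sub("^[^=]*=\\s*", "", m[1])
}

#' Write landmark configurations to a TPS file
#'
#' Coordinates are written at full double precision so that a read/write
#' round trip is exact.  When a configuration carries a `scale`, raw
#' coordinates are divided by it before writing and a `SCALE=` record is
#' emitted, mirroring how digitising software stores image calibration.
#'
#' @param configs list of configurations as returned by [read_tps()].
#' @param path output path.
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    xy <- cfg$coords
    writeLines(sprintf("LM=%d", nrow(xy)), con)
    if (!is.null(cfg$scale)) xy <- xy / cfg$scale
    writeLines(sprintf("%.17g %.17g", xy[, 1], xy[, 2]), con)
    writeLines(sprintf("ID=%s", cfg$id), con)
    if (!is.null(cfg$scale)) writeLines(sprintf("SCALE=%.17g", cfg$scale), con)
  }
  invisible(path)
}

# stack a list of configurations into an n x k x 2 array
configs_to_array <- function(configs) {
  k <- nrow(configs[[1]]$coords)
  if (!all(vapply(configs, function(c) nrow(c$coords), 0L) == k))
    stop("configurations differ in landmark count")
  arr <- array(NA_real_, c(length(configs), k, 2),
               dimnames = list(vapply(configs, `[[`, "", "id"), NULL, NULL))
  for (i in seq_along(configs)) arr[i, , ] <- configs[[i]]$coords
  arr
}

#' Centroid size of a landmark configuration
#'
#' `CS = sqrt(sum_i ||x_i - centroid||^2)`, the standard
#' geometric-morphometric size measure; invariant to rotation and
#' translation, and homogeneous of degree 1 in scale.
#'
#' @param coords k x 2 coordinate matrix (k >= 2).
#' @return centroid size in the input units (0, with a warning, for a fully
#'   degenerate configuration).
#' @export
centroid_size <- function(coords) {
  stopifnot(is.matrix(coords), nrow(coords) >= 2, ncol(coords) == 2)
  cs <- sqrt(sum(sweep(coords, 2, colMeans(coords))^2))
  if (cs == 0) warning("degenerate configuration: centroid size is 0")
  cs
}

#' Bookstein baseline registration
#'
#' Similarity transform (translation, rotation and scaling, no reflection)
#' sending landmark `p` to (0, 0) and landmark `q` to (1, 0).  Indices are
#' 1-based as in landmark files.
#'
#' @param coords k x 2 coordinate matrix.
#' @param p,q baseline landmark indices, `p != q`.
#' @return registered k x 2 coordinate matrix.
#' @export
baseline_register <- function(coords, p, q) {
  stopifnot(p != q, p >= 1, q >= 1, p <= nrow(coords), q <= nrow(coords))
  z <- complex(real = coords[, 1], imaginary = coords[, 2])
  base <- z[q] - z[p]
  if (Mod(base) == 0) stop("baseline landmarks coincide")
  w <- (z - z[p]) / base
  cbind(Re(w), Im(w))
}

# rotation (det +1) best superimposing X onto target C, both centred
.opt_rotation <- function(X, C) {
  s <- svd(crossprod(X, C))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

.center_scale <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  X / sqrt(sum(X^2))
}

#' Generalized Procrustes Analysis
#'
#' Full GPA superimposition: every configuration is centred, scaled to unit
#' centroid size, and iteratively rotated (rotation only, no reflection) onto
#' the generalized-least-squares consensus, which is recomputed as the
#' coordinate-wise mean re-centred and re-scaled to unit centroid size after
#' each pass.  Iteration stops when the root-sum-square change of the
#' consensus falls below `tol`.
#'
#' @param shapes n x k x 2 array, or a list of configurations from
#'   [read_tps()].
#' @param tol convergence tolerance on the consensus update (default 1e-8).
#' @param max_iter iteration cap; non-convergence returns the current state
#'   with `converged = FALSE` and a warning.
#' @return object of class `gpa_result`: list with `aligned` (n x k x 2),
#'   `mean_shape` (k x 2, zero centroid, unit CS), `cs` (original centroid
#'   sizes), `objective` (per-iteration sum of squared distances to the
#'   consensus), `iterations`, `converged`.
#' @export
gpa_align <- function(shapes, tol = 1e-8, max_iter = 100) {
  if (is.list(shapes) && !is.array(shapes)) shapes <- configs_to_array(shapes)
  n <- dim(shapes)[1]
  if (n < 2) stop("need >= 2 configurations")
  cs <- apply(shapes, 1, function(m) centroid_size(matrix(m, ncol = 2)))
  aligned <- shapes
  for (i in seq_len(n)) aligned[i, , ] <- .center_scale(shapes[i, , ])
  consensus <- .center_scale(apply(aligned, c(2, 3), mean))
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    for (i in seq_len(n))
      aligned[i, , ] <- aligned[i, , ] %*% .opt_rotation(aligned[i, , ], consensus)
    new_cons <- .center_scale(apply(aligned, c(2, 3), mean))
    objective <- c(objective,
                   sum(vapply(seq_len(n),
                              function(i) sum((aligned[i, , ] - new_cons)^2), 0)))
    if (sqrt(sum((new_cons - consensus)^2)) < tol) {
      consensus <- new_cons
      converged <- TRUE
      break
    }
    consensus <- new_cons
  }
  if (!converged) warning("GPA did not converge in ", max_iter, " iterations")
  structure(list(aligned = aligned, mean_shape = consensus, cs = cs,
                 objective = objective, iterations = iter,
                 converged = converged),
            class = "gpa_result")
}

#' Per-group GLS mean shapes
#'
#' Coordinate-wise means of GPA-aligned members of each group.
#'
#' @param res a `gpa_result`.
#' @param groups group label per specimen.
#' @return named list of k x 2 mean-shape matrices.
#' @export
group_mean_shapes <- function(res, groups) {
  stopifnot(length(groups) == dim(res$aligned)[1])
  lapply(split(seq_along(groups), groups), function(i)
    apply(res$aligned[i, , , drop = FALSE], c(2, 3), mean))
}

#' Full Procrustes distance between two configurations
#'
#' Root sum of squared differences after centring, unit-CS scaling and
#' optimal rotation of `a` onto `b`.
#'
#' @param a,b k x 2 coordinate matrices.
#' @return non-negative distance.
#' @export
procrustes_distance <- function(a, b) {
  a <- .center_scale(a); b <- .center_scale(b)
  sqrt(sum((a %*% .opt_rotation(a, b) - b)^2))
}

#' PCA of aligned shapes
#'
#' Principal components of the specimens x (2k) matrix of flattened
#' GPA-aligned coordinates, mean-centred.
#'
#' @param aligned n x k x 2 array of aligned coordinates (or a `gpa_result`).
#' @return list: `scores`, `explained` (non-increasing variance fractions),
#'   `rotation`, `center`.
#' @export
shape_pca <- function(aligned) {
  if (inherits(aligned, "gpa_result")) aligned <- aligned$aligned
  n <- dim(aligned)[1]
  if (n < 2) stop("need >= 2 specimens")
  X <- matrix(aligned, nrow = n)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  list(scores = pc$x, explained = v / sum(v),
       rotation = pc$rotation, center = pc$center)
}

# --- size statistics --------------------------------------------------------

#' One-way ANOVA with LSD post-hoc letters
#'
#' Standard one-way ANOVA of a measurement (typically centroid size) over
#' groups, followed by Fisher's least-significant-difference pairwise tests
#' using the pooled within-group mean square, and a compact letter display in
#' which groups sharing a letter do not differ significantly at `alpha`.
#' LSD applies no multiplicity correction by definition; set `p_adjust` to
#' any [stats::p.adjust()] method for a corrected variant.
#'
#' @param values numeric measurements.
#' @param groups group label per value (>= 2 groups, each >= 2 values).
#' @param alpha significance level for the letter display.
#' @param p_adjust p-value adjustment method (default `"none"`).
#' @return list: `F`, `df_between`, `df_within`, `p_value`, `ms_within`,
#'   `means` (data.frame with n and mean per group), `lsd` (pairwise table),
#'   `letters` (named character vector).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05, p_adjust = "none") {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 observations")
  fit <- stats::lm(values ~ groups)
  av <- stats::anova(fit)
  msw <- av["Residuals", "Mean Sq"]
  if (msw <= 1e-12 * sum(av[, "Mean Sq"]))
    stop("zero within-group variance everywhere: F undefined")
  dfw <- av["Residuals", "Df"]
  ns <- tapply(values, groups, length)
  mns <- tapply(values, groups, mean)
  labs <- levels(groups)
  pr <- utils::combn(labs, 2)
  diff <- mns[pr[1, ]] - mns[pr[2, ]]
  se <- sqrt(msw * (1 / ns[pr[1, ]] + 1 / ns[pr[2, ]]))
  tval <- diff / se
  p <- stats::p.adjust(2 * stats::pt(-abs(tval), dfw), method = p_adjust)
  lsd <- data.frame(group1 = pr[1, ], group2 = pr[2, ],
                    diff = as.numeric(diff), se = as.numeric(se),
                    t = as.numeric(tval), p = as.numeric(p),
                    significant = as.numeric(p) < alpha, row.names = NULL)
  sig <- matrix(FALSE, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(nrow(lsd)))
    sig[lsd$group1[i], lsd$group2[i]] <- sig[lsd$group2[i], lsd$group1[i]] <-
      lsd$significant[i]
  list(F = av["groups", "F value"], df_between = av["groups", "Df"],
       df_within = dfw, p_value = av["groups", "Pr(>F)"], ms_within = msw,
       means = data.frame(group = labs, n = as.integer(ns[labs]),
                          mean = as.numeric(mns[labs])),
       lsd = lsd,
       letters = .compact_letters(sig, mns[labs]))
}

# insert-and-absorb compact letter display from a pairwise significance
# matrix; groups ordered by decreasing mean
.compact_letters <- function(sig, means) {
  labs <- names(means)[order(-means)]
  cols <- list(labs)  # each column: set of mutually non-different groups
  for (g1 in labs) for (g2 in labs) {
    if (g1 >= g2 || !sig[g1, g2]) next
    split_any <- FALSE
    newcols <- list()
    for (col in cols) {
      if (all(c(g1, g2) %in% col)) {
        newcols <- c(newcols, list(setdiff(col, g1)), list(setdiff(col, g2)))
        split_any <- TRUE
      } else newcols <- c(newcols, list(col))
    }
    if (split_any) {
      # absorb columns contained in another
      keep <- rep(TRUE, length(newcols))
      for (i in seq_along(newcols)) for (j in seq_along(newcols))
        if (i != j && keep[i] && keep[j] &&
            all(newcols[[i]] %in% newcols[[j]]) &&
            !(all(newcols[[j]] %in% newcols[[i]]) && i < j))
          keep[i] <- FALSE
      cols <- newcols[keep]
    }
  }
  ord <- order(vapply(cols, function(cl) min(match(cl, labs)), 0))
  cols <- cols[ord]
  out <- stats::setNames(rep("", length(labs)), labs)
  for (i in seq_along(cols))
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters[i])
  out[names(means)]
}

#' Stepwise regression of size on geographic covariates
#'
#' Forward-stepwise ordinary least squares with backward elimination:
#' at each step the candidate covariate with the smallest partial-F p-value
#' enters if that p-value is below `alpha_enter`; after every addition any
#' included term whose partial-F p-value exceeds `alpha_remove` is removed.
#' Iteration stops when no term moves, or when the fit is numerically
#' saturated (residual sum of squares below 1e-12 of the total), so that a
#' noiseless generating model is recovered exactly.  A covariate perfectly
#' collinear with included terms yields no reduction in residual sum of
#' squares and therefore never enters.
#'
#' @param data data.frame holding the response and covariates (one row per
#'   site; >= 5 rows).
#' @param response response column name (e.g. mean centroid size per site).
#' @param covariates candidate covariate column names (default latitude,
#'   longitude, altitude).
#' @param alpha_enter,alpha_remove entry / removal thresholds.
#' @return list: `terms` (selected, in entry order), `coefficients`,
#'   `p_values` (partial-F for the retained terms), `model` (the `lm` fit).
#' @export
stepwise_cs_regression <- function(data, response = "cs",
                                   covariates = c("latitude", "longitude",
                                                  "altitude"),
                                   alpha_enter = 0.05, alpha_remove = 0.10) {
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  if (nrow(data) < 5) stop("need >= 5 sites")
  if (any(!vapply(data[c(response, covariates)],
                  function(x) all(is.finite(x)), TRUE)))
    stop("response and covariates must be finite")
  tss <- sum((data[[response]] - mean(data[[response]]))^2)
  included <- character(0)
  repeat {
    fml <- stats::reformulate(if (length(included)) included else "1",
                              response = response)
    fit <- stats::lm(fml, data = data)
    if (sum(stats::residuals(fit)^2) <= 1e-12 * tss) break
    remaining <- setdiff(covariates, included)
    changed <- FALSE
    if (length(remaining)) {
      ad <- stats::add1(fit,
                        scope = stats::reformulate(c(included, remaining)),
                        test = "F")
      pv <- ad[["Pr(>F)"]][-1]
      names(pv) <- rownames(ad)[-1]
      pv <- pv[is.finite(pv)]
      if (length(pv) && min(pv) < alpha_enter) {
        included <- c(included, names(pv)[which.min(pv)])
        changed <- TRUE
      }
    }
    if (length(included) > 1) {
      fit2 <- stats::lm(stats::reformulate(included, response = response),
                        data = data)
      dr <- stats::drop1(fit2, test = "F")
      pv <- dr[["Pr(>F)"]][-1]
      names(pv) <- rownames(dr)[-1]
      worst <- which.max(pv)
      if (length(pv) && pv[worst] > alpha_remove) {
        included <- setdiff(included, names(pv)[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- stats::lm(stats::reformulate(if (length(included)) included else "1",
                                      response = response), data = data)
  pvals <- if (length(included)) {
    dr <- stats::drop1(fit, test = "F")
    stats::setNames(dr[["Pr(>F)"]][-1], rownames(dr)[-1])[included]
  } else stats::setNames(numeric(0), character(0))
  list(terms = included, coefficients = stats::coef(fit),
       p_values = pvals, model = fit)
}
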