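# Canonical (Fisher) discriminant analysis over composition features: the
# engine behind nucleotide-composition-based host prediction. Canonical
# factors are generalized eigenvectors of the between-class scatter against
# the (ridge-regularized) pooled within-class scatter; sequences are
# projected onto them and classified to the nearest class centroid.

#' Fit a canonical discriminant model
#'
#' Computes class centroids, pooled within-class scatter `W` and
#' between-class scatter `B` (class-size weighted), regularizes `W` as
#' `W + eps I` with `eps = ridge * trace(W) / p`, and solves the generalized
#' eigenproblem `B v = lambda (W + eps I) v` via a symmetric Cholesky
#' reduction. Canonical vectors are sorted by decreasing eigenvalue, limited
#' to `min(#classes - 1, p)`, and scaled so the pooled within-class variance
#' of each canonical score is 1 — so Euclidean distance in canonical space is
#' the Mahalanobis distance of the classification geometry.
#'
#' The ridge is needed because composition features are linearly dependent
#' (the mono and dinucleotide blocks each sum to 1) and because a small class
#' (e.g. n = 5 fish controls) leaves `W` rank-deficient.
#'
#' @param features Numeric matrix, one row per sequence, p columns.
#' @param labels Class labels (character or factor), one per row.
#' @param ridge Ridge coefficient (default 1e-6).
#' @param priors `"equal"` (default) or `"proportional"`. Equal priors keep a
#'   rare class (the 5-member fish panel) callable; proportional priors would
#'   all but forbid it.
#' @return A `discriminant_model`: `classes`, `counts`, `priors`,
#'   `centroids` (class x p), `scaling` (p x ncf canonical vectors),
#'   `eigenvalues`, `centroids_canonical`, `ridge_eps`, `n`, `p`.
#' @export
fit_cda <- function(features, labels, ridge = 1e-6,
                    priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("one label per feature row required", call. = FALSE)
  classes <- sort(unique(labels))
  k <- length(classes)
  n <- nrow(x); p <- ncol(x)
  counts <- vapply(classes, function(cl) sum(labels == cl), 1L)
  if (any(counts == 0L)) stop("class with 0 members", call. = FALSE)
  if (n < k + 1L) stop("need at least #classes + 1 observations", call. = FALSE)

  centroids <- t(vapply(classes, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(p)))
  grand <- colMeans(x)
  W <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2L,
                centroids[cl == classes, ])
    W <- W + crossprod(xc)
  }
  dm <- sweep(centroids, 2L, grand)
  B <- crossprod(dm * sqrt(counts))
  tr <- sum(diag(W))
  eps <- ridge * (if (tr > 0) tr / p else 1)
  Wr <- W + diag(eps, p)

  U <- chol(Wr)
  Ui <- backsolve(U, diag(p))
  S <- crossprod(Ui, B) %*% Ui
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ncf <- min(k - 1L, p)
  lambda <- pmax(es$values[seq_len(ncf)], 0)
  V <- Ui %*% es$vectors[, seq_len(ncf), drop = FALSE]
  # unit pooled within-class variance per canonical score
  V <- V * sqrt(n - k)
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(x), paste0("CF", seq_len(ncf)))
  prior_vec <- if (priors == "equal") rep(1 / k, k) else counts / n
  names(prior_vec) <- classes
  zc <- centroids %*% V
  structure(list(classes = classes, counts = counts, priors = prior_vec,
                 centroids = centroids, scaling = V, eigenvalues = lambda,
                 centroids_canonical = zc, ridge_eps = eps, n = n, p = p),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %d classes, %d features, %d canonical factors\n",
              length(x$classes), x$p, length(x$eigenvalues)))
  cat("  classes:", paste(sprintf("%s (n=%d)", x$classes, x$counts),
                          collapse = ", "), "\n")
  cat("  eigenvalues:", paste(sprintf("%.3g", x$eigenvalues), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project features onto the canonical factors
#'
#' @param model A `discriminant_model`.
#' @param features Numeric vector (length p) or matrix (rows = queries).
#' @return Matrix of canonical coordinates (rows = queries).
#' @export
canonical_coordinates <- function(model, features) {
  x <- if (is.null(dim(features))) matrix(features, nrow = 1L)
       else as.matrix(features)
  if (ncol(x) != model$p)
    stop("feature dimension mismatch: expected ", model$p, call. = FALSE)
  x %*% model$scaling
}

#' Classify sequences by nearest class centroid in canonical space
#'
#' The per-class score is the squared Mahalanobis distance (Euclidean in the
#' scaled canonical space) minus `2 log(prior)`; the predicted host attains
#' the minimum.
#'
#' @param model A `discriminant_model`.
#' @param features Numeric vector (length p) or matrix (rows = queries).
#' @return Data frame: `predicted`, one `score_<class>` column per class,
#'   and canonical coordinates `CF1..`.
#' @export
classify <- function(model, features) {
  z <- canonical_coordinates(model, features)
  scores <- vapply(seq_along(model$classes), function(j) {
    d2 <- rowSums(sweep(z, 2L, model$centroids_canonical[j, ])^2)
    d2 - 2 * log(model$priors[j])
  }, numeric(nrow(z)))
  scores <- matrix(scores, nrow = nrow(z))
  colnames(scores) <- paste0("score_", model$classes)
  pred <- model$classes[apply(scores, 1L, which.min)]
  out <- data.frame(predicted = pred, scores, check.names = FALSE)
  cbind(out, as.data.frame(z))
}

#' Concordance of predicted and annotated host labels
#'
#' `"resubstitution"` fits on the full panel and predicts the same panel
#' (the scheme used for the published 95% figure); `"loo"` refits with each
#' sequence held out, the honest generalization estimate.
#'
#' @param features Feature matrix.
#' @param labels Annotated labels.
#' @param scheme `"resubstitution"` (default) or `"loo"`.
#' @param ... Passed to [fit_cda()].
#' @return Fraction in `[0, 1]`.
#' @export
concordance <- function(features, labels,
                        scheme = c("resubstitution", "loo"), ...) {
  scheme <- match.arg(scheme)
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (scheme == "resubstitution") {
    model <- fit_cda(x, labels, ...)
    pred <- classify(model, x)$predicted
  } else {
    pred <- vapply(seq_len(nrow(x)), function(i) {
      m <- fit_cda(x[-i, , drop = FALSE], labels[-i], ...)
      classify(m, x[i, ])$predicted
    }, "")
  }
  mean(pred == labels)
}

#' Confidence ellipse of a 2D point cloud
#'
#' Gaussian confidence ellipse around the centroid: semi-axis lengths are
#' `sqrt(eigenvalue * qchisq(level, df = 2))` of the 2D sample covariance,
#' oriented along its eigenvectors — the ellipses drawn around each host
#' group in canonical-factor projections.
#'
#' @param points n x 2 matrix of coordinates (n >= 3).
#' @param level Coverage probability in (0, 1), default 0.95.
#' @return List: `center` (length 2), `axes` (semi-axis lengths, decreasing),
#'   `angle` (radians, orientation of the major axis), `level`,
#'   `degenerate` (TRUE when the covariance is numerically singular).
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L, nrow(pts) >= 3L, level > 0, level < 1)
  center <- colMeans(pts)
  S <- stats::cov(pts)
  es <- eigen(S, symmetric = TRUE)
  degenerate <- es$values[2L] <= max(es$values[1L], 0) * 1e-12
  q <- stats::qchisq(level, df = 2L)
  axes <- sqrt(pmax(es$values, 0) * q)
  angle <- atan2(es$vectors[2L, 1L], es$vectors[1L, 1L])
  list(center = center, axes = axes, angle = angle, level = level,
       degenerate = degenerate)
}
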