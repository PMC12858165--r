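# Ridge encoding models: solver, contiguous-fold cross-validation, shared
# regularization selection across all (subject, region, condition) datasets,
# and the study-level fitting loop.

#' Ridge regression with an unpenalized intercept
#'
#' Minimizes \eqn{\|y - Xw - b\|^2 + \alpha \|w\|^2} with the intercept
#' \eqn{b} left unpenalized, via the singular value decomposition of the
#' column-centered design: \eqn{w = V\,\mathrm{diag}(d/(d^2+\alpha))\,U^T
#' (y - \bar y)}. Deterministic; \code{alpha = 0} gives the minimum-norm
#' least-squares solution.
#'
#' @param X design matrix (rows x predictors).
#' @param y response vector.
#' @param alpha ridge coefficient, \eqn{\ge 0}.
#' @return list with \code{weights} (length \code{ncol(X)}) and
#'   \code{intercept}.
#' @examples
#' X <- matrix(rnorm(60), 20); y <- X %*% c(1, -1, 0.5) + rnorm(20, sd = .1)
#' ridgeSolve(X, y, alpha = 3)$weights
#' @export
ridgeSolve <- function(X, y, alpha) {
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("non-finite values in X or y")
    if (alpha < 0) stop("alpha must be non-negative")
    y <- as.numeric(y)
    if (nrow(X) != length(y)) stop("X rows must match length(y)")
    xm <- colMeans(X)
    ym <- mean(y)
    sv <- svd(sweep(X, 2L, xm))
    d <- sv$d
    if (alpha == 0) {
        tol <- max(dim(X)) * max(d) * .Machine$double.eps
        shrink <- ifelse(d > tol, 1 / d, 0)
    } else {
        shrink <- d / (d^2 + alpha)
    }
    w <- sv$v %*% (shrink * crossprod(sv$u, y - ym))
    list(weights = as.numeric(w),
         intercept = ym - sum(xm * w))
}

# Partition base time indices into folds. base is an integer vector giving,
# for every stacked row, its position along the stimulus time axis; with
# contiguous folds, rows from all contacts at the same times land in the
# same fold.
makeFolds <- function(base, n_folds, scheme = "contiguous", seed = NULL) {
    ub <- sort(unique(base))
    if (length(ub) < n_folds)
        stop("fewer time points than folds")
    if (scheme == "contiguous") {
        cuts <- floor(seq(0, length(ub), length.out = n_folds + 1L))
        fold_of <- rep(seq_len(n_folds), diff(cuts))
    } else {
        if (!is.null(seed)) set.seed(seed)
        fold_of <- sample(rep(seq_len(n_folds),
                              length.out = length(ub)))
    }
    fold_of[match(base, ub)]
}

# Held-out Pearson r per fold for each candidate alpha, with one SVD per
# fold shared across the whole grid. Returns folds x alphas matrix.
cvCurve <- function(X, y, alphas, folds) {
    n_folds <- max(folds)
    r <- matrix(NA_real_, n_folds, length(alphas))
    for (k in seq_len(n_folds)) {
        tr <- folds != k
        xm <- colMeans(X[tr, , drop = FALSE])
        ym <- mean(y[tr])
        sv <- svd(sweep(X[tr, , drop = FALSE], 2L, xm))
        uy <- crossprod(sv$u, y[tr] - ym)
        Xte <- sweep(X[!tr, , drop = FALSE], 2L, xm)
        yte <- y[!tr]
        if (stats::sd(yte) == 0) next
        for (a in seq_along(alphas)) {
            w <- sv$v %*% ((sv$d / (sv$d^2 + alphas[a])) * uy)
            pred <- Xte %*% w + ym
            if (stats::sd(pred) == 0) next
            r[k, a] <- stats::cor(pred, yte)
        }
    }
    r
}

#' Cross-validated encoding fit at a fixed ridge coefficient
#'
#' Splits the rows into \code{n_folds} temporal segments (contiguous along
#' the stimulus time axis, aligned across contacts), fits the ridge model
#' on the training segments of each fold and computes the Pearson r between
#' predicted and measured held-out responses. The reported accuracy is the
#' mean of the per-fold r values; degenerate folds (constant held-out data)
#' yield NaN, are excluded from the mean, and trigger a warning.
#'
#' @param X design matrix (stacked rows x predictors).
#' @param y stacked response vector.
#' @param alpha ridge coefficient.
#' @param n_folds number of folds.
#' @param base optional integer vector mapping each row to its stimulus
#'   time index (defaults to row order); rows sharing a base index always
#'   share a fold.
#' @param scheme \code{"contiguous"} or \code{"random"}.
#' @param colLabels optional (feature, lag) labels for the weight columns.
#' @param subject,region,condition identifiers stored on the fit.
#' @return an [EncodingFit-class] object.
#' @export
crossvalFit <- function(X, y, alpha, n_folds = 5, base = NULL,
                        scheme = "contiguous", colLabels = NULL,
                        subject = "subject", region = "region",
                        condition = "condition") {
    y <- as.numeric(y)
    if (is.null(base)) base <- seq_along(y)
    folds <- makeFolds(base, n_folds, scheme)
    weights <- matrix(NA_real_, n_folds, ncol(X))
    intercepts <- numeric(n_folds)
    r <- rep(NaN, n_folds)
    for (k in seq_len(n_folds)) {
        tr <- folds != k
        fit <- ridgeSolve(X[tr, , drop = FALSE], y[tr], alpha)
        weights[k, ] <- fit$weights
        intercepts[k] <- fit$intercept
        pred <- X[!tr, , drop = FALSE] %*% fit$weights + fit$intercept
        if (stats::sd(y[!tr]) > 0 && stats::sd(pred) > 0)
            r[k] <- stats::cor(as.numeric(pred), y[!tr])
    }
    if (any(!is.finite(r)))
        warning("degenerate fold(s) excluded from the mean accuracy")
    new("EncodingFit", subject = subject, region = region,
        condition = condition, alpha = alpha, weights = weights,
        intercepts = intercepts, foldR = r,
        meanR = mean(r[is.finite(r)]), nRows = nrow(X),
        nContacts = nrow(X) / length(unique(base)),
        colLabels = if (is.null(colLabels)) data.frame() else colLabels)
}

#' Stack contacts of one region behind a single weight vector
#'
#' Concatenates the responses of a region's contacts along the row axis and
#' tiles the design matrix once per contact, so that one weight vector is
#' fitted to all contacts jointly. With \code{mode = "average"} the
#' contacts are averaged instead (no tiling).
#'
#' @param design a [LaggedDesign-class] for one condition.
#' @param response the matching [BinnedResponse-class].
#' @param contacts column names (or indices) of the contacts to use;
#'   default all columns.
#' @param min_contacts minimum number of contacts required.
#' @param mode \code{"concatenate"} (default) or \code{"average"}.
#' @return list with \code{X} (stacked matrix), \code{y} (stacked vector),
#'   \code{base} (stimulus time index per row, for fold alignment),
#'   \code{rowMeta}, \code{colLabels} and \code{n_contacts}.
#' @export
concatenateContacts <- function(design, response, contacts = NULL,
                                min_contacts = 1, mode = "concatenate") {
    if (is.null(contacts)) contacts <- seq_len(ncol(response@y))
    Y <- response@y[, contacts, drop = FALSE]
    nc <- ncol(Y)
    if (nc < min_contacts)
        stop(sprintf("only %d contact(s) available, %d required", nc,
                     min_contacts))
    n <- nrow(design@X)
    if (n != nrow(Y)) stop("design and response row counts differ")
    if (mode == "average") {
        return(list(X = design@X, y = rowMeans(Y), base = seq_len(n),
                    rowMeta = design@rowMeta,
                    colLabels = design@colLabels, n_contacts = nc))
    }
    idx <- rep(seq_len(n), nc)
    rowMeta <- design@rowMeta[idx, , drop = FALSE]
    rowMeta$contact <- rep(colnames(Y) %||% as.character(seq_len(nc)),
                           each = n)
    rownames(rowMeta) <- NULL
    list(X = design@X[idx, , drop = FALSE], y = as.numeric(Y),
         base = idx, rowMeta = rowMeta, colLabels = design@colLabels,
         n_contacts = nc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the single shared ridge coefficient
#'
#' Evaluates every candidate on every dataset with the same fold partition
#' (one SVD per fold, swept over the grid) and returns the grid value that
#' maximizes the unweighted mean of the cross-validated accuracies across
#' datasets. Ties break toward the smaller coefficient; the search is
#' deterministic given its inputs.
#'
#' @param datasets list of datasets as returned by
#'   [concatenateContacts()] (elements \code{X}, \code{y}, \code{base}).
#' @param grid candidate coefficients, strictly increasing.
#' @param n_folds folds per dataset.
#' @param scheme fold scheme.
#' @return the selected coefficient, with the per-alpha mean accuracy curve
#'   attached as attribute \code{curve}.
#' @export
selectSharedAlpha <- function(datasets, grid = alphaGrid(), n_folds = 5,
                              scheme = "contiguous") {
    if (!length(datasets)) stop("empty dataset list")
    curves <- vapply(datasets, function(d) {
        folds <- makeFolds(d$base %||% seq_along(d$y), n_folds, scheme)
        r <- cvCurve(d$X, d$y, grid, folds)
        colMeans(r, na.rm = TRUE)
    }, numeric(length(grid)))
    curve <- rowMeans(matrix(curves, nrow = length(grid)))
    alpha <- grid[which.max(curve)]
    attr(alpha, "curve") <- curve
    alpha
}

#' Fit encoding models for a whole study
#'
#' Builds the lagged design once from the study's feature time courses,
#' assembles one dataset per available (subject, region, condition) cell
#' with at least \code{config@min_contacts} contacts, selects the single
#' shared ridge coefficient across all cells, and cross-validates each fit.
#' Cells below the contact minimum are skipped with a message.
#'
#' @param study list with elements \code{features} (a
#'   [FeatureTimecourse-class]), \code{subjects} (data.frame with
#'   \code{id}, \code{age}, \code{group}) and \code{responses}, a nested
#'   list \code{responses[[subject_id]][[region]]} of
#'   [BinnedResponse-class] objects. [simulateCohort()] returns this shape.
#' @param config a [PipelineConfig-class] object.
#' @param regions regions to fit.
#' @param conditions conditions to fit.
#' @return list of [EncodingFit-class] objects; the shared coefficient is
#'   attached as attribute \code{alpha}.
#' @export
fitAll <- function(study, config = pipelineConfig(),
                   regions = c("DLPFC", "pSTC"),
                   conditions = c("speech", "music")) {
    design <- buildDesignMatrix(study$features, config@lags)
    cells <- list()
    for (sid in names(study$responses)) {
        for (reg in intersect(regions, names(study$responses[[sid]]))) {
            resp <- study$responses[[sid]][[reg]]
            if (ncol(resp@y) < config@min_contacts) {
                message(sprintf("skipping %s/%s: %d contact(s) < %d",
                                sid, reg, ncol(resp@y),
                                config@min_contacts))
                next
            }
            for (cond in conditions) {
                pair <- assembleCondition(design, resp, cond)
                ds <- concatenateContacts(pair$design, pair$response,
                                          min_contacts = config@min_contacts,
                                          mode = config@contact_mode)
                ds$subject <- sid
                ds$region <- reg
                ds$condition <- cond
                cells[[length(cells) + 1L]] <- ds
            }
        }
    }
    if (!length(cells)) stop("no (subject, region, condition) cell to fit")
    alpha <- selectSharedAlpha(cells, config@alpha_grid, config@n_folds,
                               config@fold_scheme)
    fits <- lapply(cells, function(d)
        crossvalFit(d$X, d$y, as.numeric(alpha), config@n_folds,
                    base = d$base, scheme = config@fold_scheme,
                    colLabels = d$colLabels, subject = d$subject,
                    region = d$region, condition = d$condition))
    attr(fits, "alpha") <- as.numeric(alpha)
    fits
}
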