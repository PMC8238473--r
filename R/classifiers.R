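# Native implementations of the five candidate classifier families:
# reduced-error-pruned decision tree, bagged random forest, naive Bayes
# with entropy-based supervised discretization, k-nearest neighbours, and a
# single-hidden-layer perceptron. Pure R, vectorized where it matters.
#
# All learners share one contract: fit on a model frame whose response is
# the binary Disease label, and predict P(Disease) in [0, 1] for any
# schema-conforming record.

# ---- model frame and encodings ---------------------------------------------

# Builds the training frame: nominal attributes become factors with an
# explicit "Missing" level (missingness is informative, e.g. unknown
# smoking status), numerics keep NA-free values (cleansed data has none;
# stray NAs are median-imputed as a safety net).
build_frame_spec <- function(data, features) {
  spec <- list(features = features, kind = list(), levels = list(),
               median = list())
  for (f in features) {
    col <- data[[f]]
    if (is.numeric(col)) {
      spec$kind[[f]] <- "numeric"
      spec$median[[f]] <- stats::median(col, na.rm = TRUE)
    } else {
      spec$kind[[f]] <- "nominal"
      v <- as.character(col)
      v[is.na(v)] <- "Missing"
      spec$levels[[f]] <- sort(unique(v))
    }
  }
  spec
}

apply_frame_spec <- function(data, spec) {
  out <- vector("list", length(spec$features))
  names(out) <- spec$features
  for (f in spec$features) {
    col <- data[[f]]
    if (is.null(col)) stop("record lacks required attribute: ", f)
    if (spec$kind[[f]] == "numeric") {
      col <- as.numeric(col)
      col[is.na(col)] <- spec$median[[f]]
      out[[f]] <- col
    } else {
      v <- as.character(col)
      v[is.na(v)] <- "Missing"
      v[!v %in% spec$levels[[f]]] <- spec$levels[[f]][1] # unseen level
      out[[f]] <- factor(v, levels = spec$levels[[f]])
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Ordinal encoding for tree-based learners: each nominal level is mapped to
# its training disease rate, turning every split search into a numeric
# threshold scan (the classical target-rate ordering device).
make_ordinal_encoder <- function(frame, y) {
  maps <- list()
  for (f in names(frame)) {
    if (is.factor(frame[[f]])) {
      rate <- tapply(y, frame[[f]], mean)
      rate[is.na(rate)] <- mean(y)
      maps[[f]] <- rate
    }
  }
  maps
}

encode_ordinal <- function(frame, maps) {
  X <- matrix(0, nrow(frame), ncol(frame),
              dimnames = list(NULL, names(frame)))
  for (j in seq_along(frame)) {
    f <- names(frame)[j]
    X[, j] <- if (is.factor(frame[[f]])) unname(maps[[f]][frame[[f]]])
              else frame[[f]]
  }
  X
}

# One-hot encoding with per-column affine scaling (for kNN and the MLP).
make_onehot_encoder <- function(frame, scale = c("range", "standard")) {
  scale <- match.arg(scale)
  cols <- list()
  for (f in names(frame)) {
    if (is.factor(frame[[f]])) {
      for (lv in levels(frame[[f]]))
        cols[[paste0(f, "=", lv)]] <- list(f = f, level = lv)
    } else {
      x <- frame[[f]]
      if (scale == "range") {
        lo <- min(x); hi <- max(x)
        cols[[f]] <- list(f = f, center = lo,
                          scale = if (hi > lo) hi - lo else 1)
      } else {
        s <- stats::sd(x)
        cols[[f]] <- list(f = f, center = mean(x),
                          scale = if (is.finite(s) && s > 0) s else 1)
      }
    }
  }
  list(cols = cols, nominal_weight = 1 / sqrt(2))
}

encode_onehot <- function(frame, enc) {
  X <- matrix(0, nrow(frame), length(enc$cols),
              dimnames = list(NULL, names(enc$cols)))
  for (j in seq_along(enc$cols)) {
    c_ <- enc$cols[[j]]
    X[, j] <- if (!is.null(c_$level))
      enc$nominal_weight * (frame[[c_$f]] == c_$level)
    else (frame[[c_$f]] - c_$center) / c_$scale
  }
  X
}

# ---- CART-style binary tree ------------------------------------------------

# Finds the best Gini split of rows `idx` over (a sample of) the features.
best_split <- function(X, y, idx, mtry, minbucket) {
  n <- length(idx)
  if (n < 2L * minbucket) return(NULL)
  p <- ncol(X)
  feats <- if (is.null(mtry) || mtry >= p) seq_len(p)
           else sample.int(p, mtry)
  best <- NULL
  best_score <- Inf
  for (j in feats) {
    x <- X[idx, j]
    o <- order(x, method = "radix")
    xs <- x[o]
    cum1 <- cumsum(y[idx][o])
    tot1 <- cum1[n]
    i <- seq_len(n - 1L)
    valid <- (xs[i] < xs[i + 1L]) & (i >= minbucket) & ((n - i) >= minbucket)
    if (!any(valid)) next
    i <- i[valid]
    nl <- i; nr <- n - i
    l1 <- cum1[i]; r1 <- tot1 - l1
    score <- l1 * (nl - l1) / nl + r1 * (nr - r1) / nr # ~ weighted Gini / 2
    k <- which.min(score)
    if (score[k] < best_score - 1e-12) {
      best_score <- score[k]
      best <- list(feature = j,
                   threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2)
    }
  }
  parent <- tot1 * (n - tot1) / n
  if (!is.null(best) && best_score >= parent - 1e-9) best <- NULL
  best
}

grow_tree <- function(X, y, minbucket = 20L, maxdepth = 30L, mtry = NULL) {
  env <- new.env(parent = emptyenv())
  env$feature <- integer(0); env$threshold <- numeric(0)
  env$left <- integer(0); env$right <- integer(0)
  env$prob <- numeric(0); env$size <- integer(0)

  new_node <- function(idx) {
    k <- length(env$feature) + 1L
    env$feature[k] <- NA_integer_; env$threshold[k] <- NA_real_
    env$left[k] <- 0L; env$right[k] <- 0L
    env$prob[k] <- (sum(y[idx]) + 1) / (length(idx) + 2) # Laplace leaf prob
    env$size[k] <- length(idx)
    k
  }
  build <- function(idx, depth) {
    k <- new_node(idx)
    pure <- sum(y[idx]) %in% c(0L, length(idx))
    if (depth < maxdepth && !pure) {
      sp <- best_split(X, y, idx, mtry, minbucket)
      if (!is.null(sp)) {
        go_left <- X[idx, sp$feature] <= sp$threshold
        env$feature[k] <- sp$feature
        env$threshold[k] <- sp$threshold
        env$left[k] <- build(idx[go_left], depth + 1L)
        env$right[k] <- build(idx[!go_left], depth + 1L)
      }
    }
    k
  }
  build(seq_len(nrow(X)), 0L)
  list(feature = env$feature, threshold = env$threshold,
       left = env$left, right = env$right,
       prob = env$prob, size = env$size)
}

# Routes rows down the tree; returns the leaf node id per row.
route_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    internal <- !is.na(tree$feature[node])
    if (!any(internal)) break
    i <- which(internal)
    nd <- node[i]
    go_left <- X[cbind(i, tree$feature[nd])] <= tree$threshold[nd]
    node[i] <- ifelse(go_left, tree$left[nd], tree$right[nd])
  }
  node
}

predict_tree <- function(tree, X) tree$prob[route_tree(tree, X)]

# Reduced-error pruning against a held-out pruning set: collapse any
# internal node whose subtree does not beat it as a leaf on pruning errors.
prune_tree_rep <- function(tree, Xp, yp) {
  node_rows <- vector("list", length(tree$feature))
  assign_rows <- function(k, rows) {
    node_rows[[k]] <<- rows
    if (!is.na(tree$feature[k])) {
      go_left <- Xp[rows, tree$feature[k]] <= tree$threshold[k]
      assign_rows(tree$left[k], rows[go_left])
      assign_rows(tree$right[k], rows[!go_left])
    }
  }
  assign_rows(1L, seq_len(nrow(Xp)))
  prune <- function(k) {
    rows <- node_rows[[k]]
    e_leaf <- sum((tree$prob[k] >= 0.5) != yp[rows])
    if (is.na(tree$feature[k])) return(e_leaf)
    e_sub <- prune(tree$left[k]) + prune(tree$right[k])
    if (e_leaf <= e_sub) {
      tree$feature[k] <<- NA_integer_
      e_leaf
    } else e_sub
  }
  prune(1L)
  tree
}

# ---- supervised discretization (entropy / MDL stopping) --------------------

entropy2 <- function(n1, n) {
  n0 <- n - n1
  h <- numeric(length(n))
  ok <- n > 0
  p1 <- ifelse(ok, n1 / pmax(n, 1), 0)
  p0 <- 1 - p1
  t1 <- ifelse(n1 > 0, -p1 * log2(pmax(p1, 1e-300)), 0)
  t0 <- ifelse(n0 > 0, -p0 * log2(pmax(p0, 1e-300)), 0)
  ifelse(ok, t1 + t0, 0)
}

# Recursive top-down binary splitting with the minimum-description-length
# acceptance criterion; returns the ordered cut points (possibly none).
mdl_cuts <- function(x, y) {
  o <- order(x, method = "radix")
  xs <- x[o]; ys <- y[o]
  cuts <- numeric(0)
  rec <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 4L) return(invisible())
    seg1 <- cumsum(ys[lo:hi])
    tot1 <- seg1[n]
    ent_s <- entropy2(tot1, n)
    i <- seq_len(n - 1L)
    valid <- xs[lo + i - 1L] < xs[lo + i]
    if (!any(valid)) return(invisible())
    i <- i[valid]
    nl <- i; nr <- n - i
    l1 <- seg1[i]; r1 <- tot1 - l1
    e_l <- entropy2(l1, nl); e_r <- entropy2(r1, nr)
    went <- (nl * e_l + nr * e_r) / n
    k <- which.min(went)
    gain <- ent_s - went[k]
    classes <- function(a, m) sum(c(a > 0, a < m)) # classes present
    kS <- classes(tot1, n); kL <- classes(l1[k], nl[k]); kR <- classes(r1[k], nr[k])
    delta <- log2(3^kS - 2) -
      (kS * ent_s - kL * e_l[k] - kR * e_r[k])
    if (gain <= (log2(n - 1) + delta) / n) return(invisible())
    cut <- (xs[lo + i[k] - 1L] + xs[lo + i[k]]) / 2
    cuts <<- c(cuts, cut)
    rec(lo, lo + i[k] - 1L)
    rec(lo + i[k], hi)
  }
  rec(1L, length(xs))
  sort(cuts)
}

# ---- learners --------------------------------------------------------------

fit_tree_family <- function(frame, y, params) {
  maps <- make_ordinal_encoder(frame, y)
  X <- encode_ordinal(frame, maps)
  prune_frac <- 1 / max(2L, params$prune_folds %||% 6L)
  if (isTRUE(params$reduced_error_pruning)) {
    # stratified grow/prune split
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    pr <- c(sample(idx1, max(1L, round(length(idx1) * prune_frac))),
            sample(idx0, max(1L, round(length(idx0) * prune_frac))))
    gr <- setdiff(seq_along(y), pr)
    tree <- grow_tree(X[gr, , drop = FALSE], y[gr],
                      minbucket = params$min_leaf %||% 20L,
                      maxdepth = params$max_depth %||% 30L)
    tree <- prune_tree_rep(tree, X[pr, , drop = FALSE], y[pr])
  } else {
    tree <- grow_tree(X, y, minbucket = params$min_leaf %||% 20L,
                      maxdepth = params$max_depth %||% 30L)
  }
  list(tree = tree, maps = maps)
}

predict_tree_family <- function(fit, frame) {
  predict_tree(fit$tree, encode_ordinal(frame, fit$maps))
}

fit_forest_family <- function(frame, y, params) {
  maps <- make_ordinal_encoder(frame, y)
  X <- encode_ordinal(frame, maps)
  n <- nrow(X); p <- ncol(X)
  ntree <- params$n_trees %||% 80L
  mtry <- params$mtry %||% max(1L, floor(log2(p)) + 1L)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(X[idx, , drop = FALSE], y[idx],
                            minbucket = params$min_leaf %||% 10L,
                            maxdepth = params$max_depth %||% 25L,
                            mtry = mtry)
  }
  list(trees = trees, maps = maps)
}

predict_forest_family <- function(fit, frame) {
  X <- encode_ordinal(frame, fit$maps)
  probs <- vapply(fit$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

fit_nb_family <- function(frame, y, params) {
  tables <- list(); cuts <- list()
  n1 <- sum(y); n0 <- length(y) - n1
  for (f in names(frame)) {
    col <- frame[[f]]
    if (is.numeric(col)) {
      cc <- if (isTRUE(params$supervised_discretization %||% TRUE))
        mdl_cuts(col, y) else
        unique(stats::quantile(col, seq(0.1, 0.9, 0.1)))
      cuts[[f]] <- cc
      col <- paste0("bin", findInterval(col, cc))
    }
    tab <- table(col, factor(y, levels = c(0, 1)))
    tables[[f]] <- list(levels = rownames(tab),
                        # Laplace-smoothed per-class level log-probabilities
                        lp0 = log((tab[, "0"] + 1) / (n0 + nrow(tab))),
                        lp1 = log((tab[, "1"] + 1) / (n1 + nrow(tab))))
  }
  list(tables = tables, cuts = cuts,
       prior1 = log((n1 + 1) / (length(y) + 2)),
       prior0 = log((n0 + 1) / (length(y) + 2)))
}

predict_nb_family <- function(fit, frame) {
  n <- nrow(frame)
  l1 <- rep(fit$prior1, n); l0 <- rep(fit$prior0, n)
  for (f in names(fit$tables)) {
    col <- frame[[f]]
    if (is.numeric(col)) {
      col <- paste0("bin", findInterval(col, fit$cuts[[f]]))
    } else col <- as.character(col)
    tb <- fit$tables[[f]]
    i <- match(col, tb$levels)
    miss <- is.na(i)
    add1 <- tb$lp1[i]; add0 <- tb$lp0[i]
    add1[miss] <- 0; add0[miss] <- 0 # unseen level carries no evidence
    l1 <- l1 + add1; l0 <- l0 + add0
  }
  1 / (1 + exp(l0 - l1))
}

fit_knn_family <- function(frame, y, params) {
  enc <- make_onehot_encoder(frame, scale = "range")
  list(enc = enc, X = encode_onehot(frame, enc), y = y,
       k = params$k %||% 20L)
}

predict_knn_family <- function(fit, frame) {
  Xte <- encode_onehot(frame, fit$enc)
  ntr <- nrow(fit$X)
  k <- min(fit$k, ntr)
  rs_tr <- rowSums(fit$X^2)
  out <- numeric(nrow(Xte))
  chunk <- 512L
  for (start in seq(1L, nrow(Xte), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(Xte))
    D <- outer(rowSums(Xte[rows, , drop = FALSE]^2), rep(1, ntr)) +
      outer(rep(1, length(rows)), rs_tr) -
      2 * Xte[rows, , drop = FALSE] %*% t(fit$X)
    for (i in seq_along(rows)) {
      nn <- order(D[i, ], method = "radix")[seq_len(k)] # index-stable ties
      out[rows[i]] <- mean(fit$y[nn])
    }
  }
  out
}

fit_mlp_family <- function(frame, y, params) {
  enc <- make_onehot_encoder(frame, scale = "standard")
  X <- encode_onehot(frame, enc)
  n <- nrow(X); d <- ncol(X)
  # hidden size "a": (number of raw attributes + number of classes) / 2
  h <- params$hidden %||% max(2L, floor((ncol(frame) + 2L) / 2L))
  lr <- params$learning_rate %||% 0.1
  mom <- params$momentum %||% 0.05
  epochs <- params$epochs %||% 100L
  batch <- params$batch_size %||% 100L

  W1 <- matrix(stats::runif(d * h, -0.5, 0.5), d, h)
  b1 <- stats::runif(h, -0.5, 0.5)
  W2 <- matrix(stats::runif(h, -0.5, 0.5), h, 1)
  b2 <- stats::runif(1, -0.5, 0.5)
  vW1 <- matrix(0, d, h); vb1 <- numeric(h); vW2 <- matrix(0, h, 1); vb2 <- 0
  sig <- function(z) 1 / (1 + exp(-z))

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      rows <- ord[start:min(start + batch - 1L, n)]
      m <- length(rows)
      Xb <- X[rows, , drop = FALSE]
      H <- sig(sweep(Xb %*% W1, 2, b1, "+"))
      p <- sig(as.vector(H %*% W2) + b2)
      # cross-entropy gradient through the logistic output
      delta <- (p - y[rows]) / m
      gW2 <- crossprod(H, delta)
      gb2 <- sum(delta)
      dH <- (delta %*% t(W2)) * H * (1 - H)
      gW1 <- crossprod(Xb, dH)
      gb1 <- colSums(dH)
      vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
      vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
    }
  }
  list(enc = enc, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

predict_mlp_family <- function(fit, frame) {
  X <- encode_onehot(frame, fit$enc)
  sig <- function(z) 1 / (1 + exp(-z))
  H <- sig(sweep(X %*% fit$W1, 2, fit$b1, "+"))
  as.vector(sig(as.vector(H %*% fit$W2) + fit$b2))
}

# ---- public fit / predict interface ----------------------------------------

family_fitters <- list(
  tree = list(fit = fit_tree_family, predict = predict_tree_family),
  forest = list(fit = fit_forest_family, predict = predict_forest_family),
  nb = list(fit = fit_nb_family, predict = predict_nb_family),
  knn = list(fit = fit_knn_family, predict = predict_knn_family),
  mlp = list(fit = fit_mlp_family, predict = predict_mlp_family)
)

#' Fit one candidate classifier
#'
#' Trains the technique described by `spec` on a clean cohort and returns a
#' model exposing a disease-probability prediction for any
#' schema-conforming record.
#'
#' @param spec A technique specification from [technique_specs()].
#' @param data Clean cohort data.frame with a `class` column.
#' @param features Character vector of feature names (default: all
#'   predictive attributes present in `data`).
#' @param seed Integer seed controlling any stochastic element of training.
#' @return An object of class `cwb_model`.
#' @export
fit_classifier <- function(spec, data, features = NULL, seed = 1L) {
  stopifnot(inherits(spec, "cwb_technique"))
  if (is.null(features))
    features <- intersect(predictive_attributes(), names(data))
  if (!"class" %in% names(data)) stop("data must contain a class column")
  y <- as.integer(data$class == "Disease")
  fs <- build_frame_spec(data, features)
  frame <- apply_frame_spec(data, fs)
  fitter <- family_fitters[[spec$family]]
  if (is.null(fitter)) stop("unknown technique family: ", spec$family)
  fit <- with_seed(seed, fitter$fit(frame, y, spec$params))
  structure(list(spec = spec, features = features, frame_spec = fs,
                 fit = fit, seed = seed),
            class = "cwb_model")
}

#' Predict disease probability
#'
#' @param model A `cwb_model` from [fit_classifier()].
#' @param newdata Data.frame with the model's feature columns.
#' @return Numeric vector of P(Disease) in `[0, 1]`.
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "cwb_model"))
  frame <- apply_frame_spec(newdata, model$frame_spec)
  p <- family_fitters[[model$spec$family]]$predict(model$fit, frame)
  pmin(pmax(p, 0), 1)
}

#' @export
print.cwb_model <- function(x, ...) {
  cat("cardiowell classifier: ", x$spec$name,
      " (", x$spec$family, ", scenario ", x$spec$scenario, ", ",
      length(x$features), " features)\n", sep = "")
  invisible(x)
}
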