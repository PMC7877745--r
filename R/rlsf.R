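# The fitted scoring model: per contact-group probability classifiers
# (kNN or single-hidden-layer feed-forward network) with a shared training
# pipeline: [0,1] rescaling -> ENN denoising -> class balancing -> grid
# search under cross-validation -> final fit.

features_for_ptype <- function(ptype) {
  if (ptype %in% DIRECTED_PTYPES) c("d", "alpha", "beta", "gamma", "delta")
  else c("d", "alpha", "gamma")
}

default_grid <- function(algorithm) {
  switch(algorithm,
         knn = lapply(c(5, 15, 51), function(k) list(k = k)),
         mlp = lapply(c(16, 32), function(s) list(size = s, decay = 0.01,
                                                  maxit = 200)))
}

# --- per-group fits ---------------------------------------------------------

knn_fit <- function(X, y, k) {
  list(k = min(k, nrow(X)), X = X, y = y)
}

knn_predict <- function(fit, Xq) {
  apply(Xq, 1, function(q) {
    d2 <- rowSums((fit$X - rep(q, each = nrow(fit$X)))^2)
    ord <- order(d2, seq_along(d2))   # distance ties broken by stored order
    mean(fit$y[ord[seq_len(fit$k)]])
  })
}

mlp_fit <- function(X, y, size, decay, maxit, seed) {
  net <- with_seed(seed,
    nnet::nnet(x = X, y = as.numeric(y), size = size, decay = decay,
               maxit = maxit, entropy = TRUE, trace = FALSE))
  list(size = size, n_in = ncol(X), wts = net$wts)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Explicit forward pass through the nnet weight vector (hidden units first,
# each (bias, w_1..w_p); then output (bias, v_1..v_h)).
mlp_predict <- function(fit, Xq) {
  p <- fit$n_in; h <- fit$size
  W <- matrix(fit$wts[seq_len(h * (p + 1))], nrow = p + 1)
  v <- fit$wts[h * (p + 1) + seq_len(h + 1)]
  Z <- sigmoid(cbind(1, Xq) %*% W)
  as.numeric(sigmoid(cbind(1, Z) %*% v))
}

fit_config <- function(algorithm, X, y, config, seed) {
  if (algorithm == "knn") knn_fit(X, y, config$k)
  else mlp_fit(X, y, config$size, config$decay, config$maxit, seed)
}

predict_fit <- function(algorithm, fit, Xq) {
  if (nrow(Xq) == 0) return(numeric())
  if (algorithm == "knn") knn_predict(fit, Xq)
  else mlp_predict(fit, Xq)
}

#' Train the coarse-grained RNA-ligand scoring model
#'
#' Fits one probability classifier per contact group (base x RNA bead x
#' pharmacophore type) from a labelled contact table.  Groups with fewer
#' than \code{min_pos} positive contacts are dropped (and listed in the
#' manifest).  Within each retained group the pipeline is: rescale features
#' to [0,1], remove label noise with Edited Nearest Neighbours, undersample
#' the majority class to balance, select hyperparameters by held-out accuracy
#' under cross-validation (ligand-cluster folds when \code{clusters} is
#' given, otherwise seeded stratified folds), and refit on all retained
#' records.
#'
#' @param contacts data.frame with columns base, bead, ptype (or key), the
#'   descriptors d, alpha, beta, gamma, delta, a \code{label} column
#'   ("positive"/"negative"), and optionally \code{complex_id}.
#' @param algorithm \code{"knn"} or \code{"mlp"}.
#' @param grid list of hyperparameter configurations (named lists); default
#'   k in \{5, 15, 51\} for kNN, hidden size in \{16, 32\} for the network.
#' @param clusters optional named integer vector mapping complex_id to a
#'   ligand-cluster id, defining the cross-validation folds.
#' @param seed integer; all stochastic steps derive from it.
#' @param min_pos minimum positive contacts for a group to be modelled
#'   (default 10).
#' @param enn_k ENN neighbourhood size (default 3).
#' @param cv_folds fold count when \code{clusters} is absent (default 5).
#' @return An object of class \code{"rlsf"} with \code{predict},
#'   \code{print} and \code{summary} methods.
#' @export
rlsf_train <- function(contacts, algorithm = c("knn", "mlp"), grid = NULL,
                       clusters = NULL, seed = 1, min_pos = 10, enn_k = 3,
                       cv_folds = 5) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (nrow(contacts) == 0) stop_data("empty contact table")
  if (is.null(contacts$label) || !any(contacts$label %in% c("positive", "negative")))
    stop_data("contacts carry no positive/negative labels")
  df <- contacts[contacts$label %in% c("positive", "negative"), , drop = FALSE]
  if (is.null(df$key)) df$key <- paste(df$base, df$bead, df$ptype, sep = ":")
  groups <- split(seq_len(nrow(df)), df$key)

  bundles <- list()
  man <- list()
  for (gi in seq_along(groups)) {
    key <- names(groups)[gi]
    idx <- groups[[gi]]
    ptype <- strsplit(key, ":")[[1]][3]
    feats <- features_for_ptype(ptype)
    X <- as.matrix(df[idx, feats, drop = FALSE])
    ok <- stats::complete.cases(X)
    X <- X[ok, , drop = FALSE]
    y <- df$label[idx][ok] == "positive"
    cid <- if (!is.null(df$complex_id)) df$complex_id[idx][ok] else rep("x", sum(ok))
    n_pos <- sum(y); n_neg <- sum(!y)
    gseed <- (seed * 131 + hash_string(key, 10000)) %% 2147483647
    if (n_pos < min_pos) {
      man[[key]] <- data.frame(key = key, status = "dropped", n_pos = n_pos,
                               n_neg = n_neg, n_retained = 0L,
                               config = NA_character_, cv_accuracy = NA_real_)
      next
    }
    if (n_neg == 0)
      stop_data("group %s has no negative records; cannot train", key)
    scaler <- fit_scaler(X)
    Xs <- apply_scaler(scaler, X)
    surv <- suppressWarnings(enn_filter(Xs, y, k = enn_k))
    # ENN may eat a whole class in pathological toy sets; fall back to all rows
    if (length(unique(y[surv])) < 2) surv <- seq_along(y)
    bal <- balance_classes(ifelse(y[surv], "positive", "negative"), seed = gseed)
    ret <- surv[bal]
    Xr <- Xs[ret, , drop = FALSE]; yr <- y[ret]; cr <- cid[ret]

    folds <- make_folds(yr, cr, clusters, cv_folds, gseed)
    cv <- vapply(grid, function(cfg) cv_accuracy(algorithm, Xr, yr, folds,
                                                 cfg, gseed), numeric(1))
    best <- which.max(cv)   # first configuration on ties
    fit <- fit_config(algorithm, Xr, yr, grid[[best]], gseed)
    bundles[[key]] <- list(key = key, features = feats, scaler = scaler,
                           algorithm = algorithm, config = grid[[best]],
                           fit = fit, n_pos = n_pos, n_neg = n_neg)
    man[[key]] <- data.frame(key = key, status = "retained", n_pos = n_pos,
                             n_neg = n_neg, n_retained = length(ret),
                             config = config_string(grid[[best]]),
                             cv_accuracy = cv[best])
  }
  if (length(bundles) == 0) stop_data("no contact group survived training")
  manifest <- do.call(rbind, man)
  rownames(manifest) <- NULL
  structure(list(algorithm = algorithm, groups = bundles, manifest = manifest,
                 seed = seed, min_pos = min_pos, enn_k = enn_k,
                 n_records = nrow(df)),
            class = "rlsf")
}

config_string <- function(cfg) paste(names(cfg), unlist(cfg), sep = "=", collapse = ";")

make_folds <- function(y, complex_id, clusters, cv_folds, seed) {
  if (!is.null(clusters)) {
    f <- unname(clusters[complex_id])
    if (anyNA(f)) stop_data("complex_id missing from ligand-cluster map")
    return(as.integer(f))
  }
  n <- length(y)
  f <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  })
  f
}

cv_accuracy <- function(algorithm, X, y, folds, config, seed) {
  correct <- 0; total <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || sum(tr) < 2) next
    fit <- fit_config(algorithm, X[tr, , drop = FALSE], y[tr], config, seed)
    p <- predict_fit(algorithm, fit, X[!tr, , drop = FALSE])
    correct <- correct + sum((p >= 0.5) == y[!tr])
    total <- total + sum(!tr)
  }
  if (total == 0) return(0)
  correct / total
}

#' Predict interaction probabilities for contact records
#'
#' Looks up the contact group of each record and applies that group's
#' classifier to its (rescaled) descriptors.  Records in groups without a
#' model, or with missing required descriptors, get NA.
#'
#' @param object an \code{rlsf} model.
#' @param newdata contact data.frame (as from \code{\link{enumerate_contacts}}).
#' @param ... unused.
#' @return numeric vector of probabilities in [0,1] (NA where unscored).
#' @export
predict.rlsf <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(numeric())
  key <- newdata$key
  if (is.null(key)) key <- paste(newdata$base, newdata$bead, newdata$ptype, sep = ":")
  p <- rep(NA_real_, nrow(newdata))
  for (k in unique(key)) {
    bundle <- object$groups[[k]]
    if (is.null(bundle)) next
    rows <- which(key == k)
    X <- as.matrix(newdata[rows, bundle$features, drop = FALSE])
    ok <- stats::complete.cases(X)
    if (!any(ok)) next
    Xs <- apply_scaler(bundle$scaler, X[ok, , drop = FALSE])
    Xs[Xs < 0] <- 0; Xs[Xs > 1] <- 1
    p[rows[ok]] <- predict_fit(bundle$algorithm, bundle$fit, Xs)
  }
  p
}

#' @export
print.rlsf <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<rlsf> %s scoring model: %d/%d contact groups modelled (%d dropped)\n",
              toupper(x$algorithm), sum(m$status == "retained"), nrow(m),
              sum(m$status == "dropped")))
  cat(sprintf("  trained on %d labelled contacts, seed %d\n", x$n_records, x$seed))
  invisible(x)
}

#' @export
summary.rlsf <- function(object, ...) {
  m <- object$manifest
  acc <- m$cv_accuracy[m$status == "retained"]
  out <- list(algorithm = object$algorithm, manifest = m,
              n_retained = sum(m$status == "retained"),
              n_dropped = sum(m$status == "dropped"),
              cv_accuracy = stats::quantile(acc, c(0, 0.25, 0.5, 0.75, 1)))
  class(out) <- "summary.rlsf"
  out
}

#' @export
print.summary.rlsf <- function(x, ...) {
  cat(sprintf("Coarse-grained RNA-ligand scoring model (%s)\n", toupper(x$algorithm)))
  cat(sprintf("Groups: %d modelled, %d dropped (under the positive-contact threshold)\n",
              x$n_retained, x$n_dropped))
  cat("Cross-validated accuracy over groups:\n")
  print(round(x$cv_accuracy, 3))
  invisible(x)
}

# --- model archive ----------------------------------------------------------

sanitize_key <- function(key) gsub("'", "p", gsub(":", "_", key))

#' Write a trained model to a text archive directory
#'
#' The archive holds a JSON manifest (schema version, per-group metadata,
#' scaler ranges, checksums) plus one parameter file per group: the scaled
#' kNN reference set as CSV, or the network weight vector as JSON.  Archives
#' are byte-reproducible for identical training inputs and seeds.
#'
#' @param model an \code{rlsf}.
#' @param dir target directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_rlsf <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (key in names(model$groups)) {
    b <- model$groups[[key]]
    fname <- paste0(sanitize_key(key), if (b$algorithm == "knn") ".csv" else ".json")
    path <- file.path(dir, fname)
    if (b$algorithm == "knn") {
      ref <- as.data.frame(b$fit$X)
      names(ref) <- b$features
      ref$positive <- as.integer(b$fit$y)
      utils::write.csv(format(ref, digits = 15, trim = TRUE, scientific = FALSE),
                       path, row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(list(size = b$fit$size, n_in = b$fit$n_in,
                                wts = b$fit$wts),
                           path, digits = NA, auto_unbox = TRUE)
    }
    entries[[key]] <- list(
      key = key, file = fname, algorithm = b$algorithm,
      features = b$features,
      scaler_min = unname(b$scaler$min), scaler_max = unname(b$scaler$max),
      config = b$config, n_pos = b$n_pos, n_neg = b$n_neg,
      checksum = rls_checksum(readLines(path, warn = FALSE)))
  }
  manifest <- list(
    format_version = 1L,
    package = "rligscore",
    algorithm = model$algorithm,
    seed = model$seed, min_pos = model$min_pos, enn_k = model$enn_k,
    n_records = model$n_records,
    groups = unname(entries),
    dropped = model$manifest[model$manifest$status == "dropped",
                             c("key", "n_pos", "n_neg")],
    archive_hash = rls_checksum(vapply(entries, `[[`, "", "checksum")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  # the human-readable manifest table travels with the archive
  utils::write.csv(model$manifest, file.path(dir, "groups.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a model archive written by \code{\link{write_rlsf}}
#'
#' Per-group checksums and the archive hash are verified; any mismatch is a
#' data error naming the offending file.
#'
#' @param dir archive directory.
#' @return an \code{rlsf} model.
#' @export
read_rlsf <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_data("no manifest.json in archive '%s'", dir)
  man <- tryCatch(jsonlite::read_json(mpath, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e)
                    stop_data("corrupt archive manifest '%s': %s", mpath,
                              conditionMessage(e)))
  if (is.null(man$groups) || is.null(man$archive_hash))
    stop_data("corrupt archive manifest '%s': missing fields", mpath)
  sums <- vapply(man$groups, function(e) e$checksum, "")
  if (!identical(rls_checksum(sums), man$archive_hash))
    stop_data("corrupt archive manifest '%s': archive hash mismatch", mpath)
  bundles <- list()
  rows <- list()
  for (e in man$groups) {
    path <- file.path(dir, e$file)
    if (!file.exists(path)) stop_data("archive file missing: '%s'", path)
    if (!identical(rls_checksum(readLines(path, warn = FALSE)), e$checksum))
      stop_data("checksum mismatch for archive file '%s'", path)
    feats <- unlist(e$features)
    scaler <- list(min = stats::setNames(unlist(e$scaler_min), feats),
                   max = stats::setNames(unlist(e$scaler_max), feats))
    if (e$algorithm == "knn") {
      ref <- utils::read.csv(path)
      fit <- knn_fit(as.matrix(ref[, feats, drop = FALSE]),
                     ref$positive == 1, e$config$k)
    } else {
      pj <- jsonlite::read_json(path, simplifyVector = TRUE)
      fit <- list(size = pj$size, n_in = pj$n_in, wts = pj$wts)
    }
    bundles[[e$key]] <- list(key = e$key, features = feats, scaler = scaler,
                             algorithm = e$algorithm, config = e$config,
                             fit = fit, n_pos = e$n_pos, n_neg = e$n_neg)
    rows[[e$key]] <- data.frame(key = e$key, status = "retained",
                                n_pos = e$n_pos, n_neg = e$n_neg,
                                n_retained = if (e$algorithm == "knn") nrow(ref) else NA_integer_,
                                config = config_string(e$config),
                                cv_accuracy = NA_real_)
  }
  dropped <- man$dropped
  if (!is.null(dropped) && length(dropped) > 0) {
    dd <- as.data.frame(do.call(rbind, lapply(dropped, as.data.frame)))
    for (i in seq_len(nrow(dd)))
      rows[[length(rows) + 1]] <- data.frame(key = dd$key[i], status = "dropped",
                                             n_pos = dd$n_pos[i], n_neg = dd$n_neg[i],
                                             n_retained = 0L, config = NA_character_,
                                             cv_accuracy = NA_real_)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(algorithm = man$algorithm, groups = bundles,
                 manifest = manifest, seed = man$seed, min_pos = man$min_pos,
                 enn_k = man$enn_k, n_records = man$n_records,
                 archive_hash = man$archive_hash),
            class = "rlsf")
}
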