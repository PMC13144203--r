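# Fit serialization: a fit is written as a directory of plain CSV matrices
# plus a JSON metadata file.  Matrices are written with 17 significant
# digits, which round-trips IEEE doubles exactly, so read_fit recovers every
# value bit for bit.

format_full <- function(x)
  formatC(x, digits = 17, format = "g")

write_matrix_csv <- function(A, path) {
  A <- as.matrix(A)
  lines <- apply(A, 1, function(r) paste(format_full(r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_csv <- function(path) {
  if (!file.exists(path))
    stop("missing fit component: ", path)
  lines <- readLines(path)
  if (length(lines) == 0)
    stop("malformed fit file (empty): ", path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  nc <- length(rows[[1]])
  if (any(lengths(rows) != nc))
    stop("malformed fit file (ragged rows): ", path)
  A <- do.call(rbind, lapply(rows, as.numeric))
  if (any(!is.finite(A)))
    stop("malformed fit file (non-numeric entries): ", path)
  A
}

#' Write a fit to a directory
#'
#' Serializes a \code{"poisson_nmf_fit"} or \code{"topic_model_fit"} as a
#' directory of CSV matrices plus a \code{meta.json} file holding scalars,
#' the optimization trace and the class. The layout is lossless:
#' \code{\link{read_fit}} reconstructs every matrix bit-identically.
#'
#' For a topic model fit the directory contains \code{L.csv}, \code{F.csv},
#' \code{s.csv}, \code{u.csv} together with the underlying Poisson NMF
#' matrices \code{H.csv}, \code{W.csv}, the progress table
#' \code{progress.csv} and \code{meta.json}; a Poisson NMF fit omits the
#' topic-model files.
#'
#' @param fit The fit object.
#' @param path Directory to create (overwritten if it exists).
#'
#' @return Invisibly, the directory path.
#'
#' @importFrom jsonlite write_json read_json
#' @importFrom utils write.csv read.csv
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, c("poisson_nmf_fit", "topic_model_fit")))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(class = class(fit)[1], k = fit$k,
               objective = fit$objective, loglik = fit$loglik,
               trace = fit$trace)
  if (inherits(fit, "topic_model_fit")) {
    write_matrix_csv(fit$L, file.path(path, "L.csv"))
    write_matrix_csv(fit$F, file.path(path, "F.csv"))
    write_matrix_csv(cbind(fit$s), file.path(path, "s.csv"))
    write_matrix_csv(cbind(fit$u), file.path(path, "u.csv"))
    write_matrix_csv(fit$pnmf$H, file.path(path, "H.csv"))
    write_matrix_csv(fit$pnmf$W, file.path(path, "W.csv"))
    meta$pnmf <- list(objective = fit$pnmf$objective,
                      loglik = fit$pnmf$loglik, kkt = fit$pnmf$kkt,
                      method = fit$pnmf$method, seed = fit$pnmf$seed)
  } else {
    write_matrix_csv(fit$H, file.path(path, "H.csv"))
    write_matrix_csv(fit$W, file.path(path, "W.csv"))
    meta$kkt <- fit$kkt
    meta$method <- fit$method
    meta$seed <- fit$seed
  }
  write.csv(progress_report(fit), file.path(path, "progress.csv"),
            row.names = FALSE)
  write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
             digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a fit from a directory
#'
#' Reconstructs a fit written by \code{\link{write_fit}}.
#'
#' @param path Directory produced by \code{\link{write_fit}}.
#'
#' @return A \code{"poisson_nmf_fit"} or \code{"topic_model_fit"}, matching
#'   what was written.
#'
#' @export
read_fit <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a fit directory (no meta.json): ", path)
  meta <- read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$class) ||
      !meta$class %in% c("poisson_nmf_fit", "topic_model_fit"))
    stop("malformed fit metadata in ", meta_path)
  trace <- as.data.frame(meta$trace)
  if (meta$class == "poisson_nmf_fit") {
    fit <- list(H = read_matrix_csv(file.path(path, "H.csv")),
                W = read_matrix_csv(file.path(path, "W.csv")),
                k = meta$k, objective = meta$objective,
                loglik = meta$loglik, kkt = meta$kkt, trace = trace,
                method = meta$method, seed = meta$seed)
    return(structure(fit, class = "poisson_nmf_fit"))
  }
  pnmf <- structure(list(H = read_matrix_csv(file.path(path, "H.csv")),
                         W = read_matrix_csv(file.path(path, "W.csv")),
                         k = meta$k, objective = meta$pnmf$objective,
                         loglik = meta$pnmf$loglik, kkt = meta$pnmf$kkt,
                         trace = trace, method = meta$pnmf$method,
                         seed = meta$pnmf$seed),
                    class = "poisson_nmf_fit")
  fit <- list(L = read_matrix_csv(file.path(path, "L.csv")),
              F = read_matrix_csv(file.path(path, "F.csv")),
              s = drop(read_matrix_csv(file.path(path, "s.csv"))),
              u = drop(read_matrix_csv(file.path(path, "u.csv"))),
              k = meta$k, objective = meta$objective, loglik = meta$loglik,
              trace = trace, pnmf = pnmf)
  structure(fit, class = "topic_model_fit")
}
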