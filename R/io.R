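#' Write a model or dataset container to disk
#'
#' Plain-text sidecar container: a directory holding a JSON manifest
#' (`manifest.json` with group structure, dimensions and metadata) and one
#' CSV per matrix. Groups mirror the hierarchical layout
#' `params/{A,B,C,W,V,B0,W1}` and `data/{Y,U,U0,labels,meta}`; 3-d arrays
#' are stored as one CSV per group with trials stacked row-wise and their
#' dimensions recorded in the manifest.
#'
#' @param params an `ssm_params`, or `NULL`.
#' @param data an `epoched_dataset`, or `NULL`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, params = NULL, data = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = "taskdyn-container", version = 1L)
  wcsv <- function(M, name) {
    utils::write.table(M, file.path(path, paste0(name, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(params)) {
    validate_ssm_params(params)
    for (nm in c("A", "B", "C", "W", "V", "B0", "W1"))
      wcsv(params[[nm]], paste0("params_", nm))
    manifest$params <- lapply(params[c("A", "B", "C", "W", "V", "B0", "W1")], dim)
  }
  if (!is.null(data)) {
    flat3 <- function(X) {           # (n, d, T) -> (n*T) x d, t-major blocks
      d <- dim(X)
      out <- matrix(0, d[1] * d[3], d[2])
      for (t in seq_len(d[3]))
        out[(t - 1) * d[1] + seq_len(d[1]), ] <- matrix(X[, , t], nrow = d[1])
      out
    }
    wcsv(flat3(data$Y), "data_Y")
    if (dim(data$U)[2] > 0) wcsv(flat3(data$U), "data_U")
    wcsv(data$U0, "data_U0")
    if (ncol(data$labels) > 0)
      utils::write.csv(data$labels, file.path(path, "data_labels.csv"),
                       row.names = FALSE)
    manifest$data <- list(dim_Y = dim(data$Y), dim_U = dim(data$U),
                          dim_U0 = dim(data$U0), meta = data$meta)
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_container
#' @return `read_container()`: list with elements `params` and/or `data`.
#' @export
read_container <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  rcsv <- function(name)
    as.matrix(utils::read.table(file.path(path, paste0(name, ".csv")),
                                sep = ",", header = FALSE))
  out <- list()
  if (!is.null(manifest$params)) {
    ps <- lapply(c(A = "A", B = "B", C = "C", W = "W", V = "V",
                   B0 = "B0", W1 = "W1"), function(nm) {
      M <- rcsv(paste0("params_", nm))
      dm <- unlist(manifest$params[[nm]])
      matrix(as.numeric(M), dm[1], dm[2])
    })
    out$params <- ssm_params(ps$A, ps$B, ps$C, ps$W, ps$V, ps$B0, ps$W1)
  }
  if (!is.null(manifest$data)) {
    unflat3 <- function(M, dm) {
      X <- array(0, dim = dm)
      for (t in seq_len(dm[3]))
        X[, , t] <- M[(t - 1) * dm[1] + seq_len(dm[1]), , drop = FALSE]
      X
    }
    dy <- unlist(manifest$data$dim_Y); du <- unlist(manifest$data$dim_U)
    Y <- unflat3(rcsv("data_Y"), dy)
    U <- if (du[2] > 0) unflat3(rcsv("data_U"), du) else array(0, du)
    U0 <- rcsv("data_U0")
    lab_file <- file.path(path, "data_labels.csv")
    labels <- if (file.exists(lab_file)) utils::read.csv(lab_file) else NULL
    out$data <- epoched_dataset(Y = Y, U = U, U0 = U0, labels = labels,
                                meta = manifest$data$meta)
  }
  out
}
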