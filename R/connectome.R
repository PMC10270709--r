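#' Structural connectome container
#'
#' Bundles a nonnegative inter-regional connectivity matrix `C`, a symmetric
#' inter-regional distance matrix `D` (millimeters, zero diagonal), region
#' labels, and a logical cortical mask selecting the regions used when
#' averaging goodness of fit (in the Desikan-Killiany atlas, 68 cortical of
#' 86 total regions). Rows of `C` are normalized by their row degree so every
#' connected row sums to 1; zero-degree rows are left all-zero and flagged by
#' [validate_connectome()].
#'
#' @param C Square nonnegative connectivity matrix.
#' @param D Square symmetric distance matrix, mm, zero diagonal.
#' @param labels Character vector of region names; defaults to
#'   `"R1" ... "RN"`.
#' @param cortical_mask Logical vector marking cortical regions; defaults to
#'   all `TRUE`.
#' @param normalize If `TRUE` (default), rows of `C` are divided by their row
#'   sums on construction; pass `FALSE` for matrices already normalized.
#' @return An object of class `connectome` with fields `C`, `D`, `labels`,
#'   `cortical_mask`, `N`.
#' @export
connectome <- function(C, D, labels = NULL, cortical_mask = NULL,
                       normalize = TRUE) {
  C <- as.matrix(C); D <- as.matrix(D)
  if (nrow(C) != ncol(C))
    stop(sprintf("C must be square, got %d x %d", nrow(C), ncol(C)))
  if (!all(dim(D) == dim(C)))
    stop(sprintf("D (%d x %d) must match C (%d x %d)",
                 nrow(D), ncol(D), nrow(C), ncol(C)))
  if (any(C < 0)) stop("C must be nonnegative")
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))))
    stop("D must be symmetric")
  N <- nrow(C)
  if (is.null(labels)) labels <- paste0("R", seq_len(N))
  if (is.null(cortical_mask)) cortical_mask <- rep(TRUE, N)
  if (length(labels) != N || length(cortical_mask) != N)
    stop("labels and cortical_mask must have one entry per region")
  if (normalize) {
    deg <- rowSums(C)
    nz <- deg > 0
    C[nz, ] <- C[nz, , drop = FALSE] / deg[nz]
  }
  dimnames(C) <- NULL
  dimnames(D) <- NULL
  structure(list(C = C, D = D, labels = labels,
                 cortical_mask = as.logical(cortical_mask), N = N),
            class = "connectome")
}

#' Validate a connectome
#'
#' Checks row-degree normalization (connected rows sum to 1 within
#' tolerance), nonnegativity of `C`, symmetry and zero diagonal of `D`, and
#' reports zero-degree (disconnected) rows.
#'
#' @param conn A [connectome()] object.
#' @param tol Row-sum tolerance.
#' @return Invisibly, a list with `ok` (logical) and a character vector
#'   `problems`; `zero_degree_rows` lists disconnected rows (informational,
#'   not an error).
#' @export
validate_connectome <- function(conn, tol = 1e-10) {
  problems <- character(0)
  rs <- rowSums(conn$C)
  nz <- rs > 0
  if (any(abs(rs[nz] - 1) > tol))
    problems <- c(problems, sprintf(
      "%d connected row(s) of C do not sum to 1 (max deviation %.3g)",
      sum(abs(rs[nz] - 1) > tol), max(abs(rs[nz] - 1))))
  if (any(conn$C < 0)) problems <- c(problems, "C has negative entries")
  if (max(abs(conn$D - t(conn$D))) > 1e-8 * max(1, max(abs(conn$D))))
    problems <- c(problems, "D is not symmetric")
  if (any(abs(diag(conn$D)) > 0))
    problems <- c(problems, "D has nonzero diagonal entries")
  res <- list(ok = length(problems) == 0, problems = problems,
              zero_degree_rows = which(!nz))
  invisible(res)
}

#' @export
print.connectome <- function(x, ...) {
  v <- validate_connectome(x)
  cat(sprintf("Connectome: %d regions (%d cortical)\n",
              x$N, sum(x$cortical_mask)))
  cat(sprintf("  distance range: %.1f - %.1f mm\n",
              min(x$D[upper.tri(x$D)]), max(x$D)))
  cat(if (v$ok) "  validation: OK\n"
      else paste0("  validation problems: ",
                  paste(v$problems, collapse = "; "), "\n"))
  if (length(v$zero_degree_rows))
    cat(sprintf("  zero-degree rows: %s\n",
                paste(v$zero_degree_rows, collapse = ", ")))
  invisible(x)
}

#' Read a connectome from CSV files
#'
#' Expects two square numeric CSV matrices with region labels as the header
#' row: the connectivity matrix and the distance matrix. An optional
#' single-column mask file marks cortical regions (1/0 or TRUE/FALSE per
#' region, header line `cortical`).
#'
#' @param c_path Path to the connectivity CSV.
#' @param d_path Path to the distance CSV.
#' @param mask_path Optional path to the cortical mask CSV.
#' @param normalize Normalize rows by row degree on load (default `TRUE`; a
#'   notice is emitted when normalization changed any row).
#' @return A [connectome()] object.
#' @export
read_connectome <- function(c_path, d_path, mask_path = NULL,
                            normalize = TRUE) {
  C <- as.matrix(utils::read.csv(c_path, check.names = FALSE))
  D <- as.matrix(utils::read.csv(d_path, check.names = FALSE))
  if (nrow(C) != ncol(C))
    stop(sprintf("connectivity CSV is not square: %d rows x %d columns",
                 nrow(C), ncol(C)))
  if (!is.numeric(C) || !is.numeric(D))
    stop("connectome CSVs must be numeric")
  labels <- colnames(C)
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- as.logical(utils::read.csv(mask_path)[[1]])
  }
  if (normalize) {
    rs <- rowSums(C)
    if (any(abs(rs[rs > 0] - 1) > 1e-10))
      message("read_connectome: rows of C re-normalized by row degree")
  }
  connectome(C, D, labels = labels, cortical_mask = mask,
             normalize = normalize)
}

#' Write a connectome to CSV files
#'
#' @param conn A [connectome()] object.
#' @param c_path,d_path,mask_path Output paths; the mask is written only when
#'   `mask_path` is given.
#' @return Invisibly, `conn`.
#' @export
write_connectome <- function(conn, c_path, d_path, mask_path = NULL) {
  cm <- conn$C; dimnames(cm) <- list(NULL, conn$labels)
  dm <- conn$D; dimnames(dm) <- list(NULL, conn$labels)
  utils::write.csv(cm, c_path, row.names = FALSE)
  utils::write.csv(dm, d_path, row.names = FALSE)
  if (!is.null(mask_path))
    utils::write.csv(data.frame(cortical = as.integer(conn$cortical_mask)),
                     mask_path, row.names = FALSE)
  invisible(conn)
}
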