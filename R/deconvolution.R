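# Fractional-identity deconvolution.
#
# Each cell's transcriptome x is decomposed against k signature profiles S
# (genes x k, mean linear FPKM of reference populations) by solving
#
#   minimize  || x - S f ||_2^2   subject to  f >= 0,  sum(f) = 1.
#
# The fitted simplex vector f is the cell's "fractional identity": how much
# of each reference identity its transcriptome carries. The solver is a
# deterministic active-set method on the simplex: solve the
# equality-constrained least squares on the current support, drop the most
# negative component to the boundary, and when the support is feasible check
# the KKT conditions of the zero components, re-admitting any whose gradient
# would improve the fit.

#' Signature set container
#'
#' @param profiles Non-negative genes x states matrix of mean FPKM with
#'   column names (state labels) and row names or a `gene_ids` argument.
#' @param gene_ids Character gene ids (defaults to `rownames(profiles)`).
#' @return A `signature_set` with fields `profiles`, `gene_ids`, `names`.
#' @export
signature_set <- function(profiles, gene_ids = rownames(profiles)) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop_config("need at least 2 signature states")
  if (is.null(colnames(profiles))) stop_config("profiles need state names")
  if (is.null(gene_ids)) stop_config("profiles need gene ids")
  if (min(profiles) < 0) stop_config("signature profiles must be non-negative")
  if (any(colSums(profiles) == 0)) stop_config("all-zero signature column")
  rownames(profiles) <- gene_ids
  structure(list(profiles = profiles, gene_ids = as.character(gene_ids),
                 names = colnames(profiles)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d genes x %d states (%s)\n",
              nrow(x$profiles), ncol(x$profiles),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Build one signature column as a group mean
#'
#' The signature of a reference population is the arithmetic mean FPKM of its
#' samples, gene by gene.
#'
#' @param x An `expression_matrix` with unit `"fpkm"`.
#' @param cells Non-empty character vector of member cell/sample ids.
#' @param name State label for the column.
#' @return Named numeric vector (one value per gene) with attribute `state`.
#' @export
make_signature <- function(x, cells, name) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$unit != "fpkm") stop_config("signatures are built from fpkm, got ",
                                    x$unit)
  if (length(cells) == 0) stop_config("empty sample group for signature '",
                                      name, "'")
  sub <- subset_matrix(x, cells = cells)
  out <- rowMeans(sub$values)
  names(out) <- x$gene_ids
  attr(out, "state") <- name
  out
}

#' Combine signature columns built by [make_signature()]
#'
#' @param ... Named vectors from [make_signature()] over the same genes.
#' @return A `signature_set`.
#' @export
combine_signatures <- function(...) {
  cols <- list(...)
  labs <- vapply(cols, function(v) attr(v, "state"), character(1))
  profiles <- do.call(cbind, lapply(cols, as.numeric))
  colnames(profiles) <- labs
  signature_set(profiles, gene_ids = names(cols[[1]]))
}

#' Simplex-constrained least-squares deconvolution of one vector
#'
#' Solves `min || x - S f ||^2` over the probability simplex by a
#' deterministic active-set iteration (tolerance 1e-10, at most `10 k`
#' support changes). Duplicate signature columns make the optimum non-unique;
#' they are detected up front, solved as one merged column, and the fitted
#' fraction is split evenly among the duplicates with `non_unique = TRUE`.
#'
#' @param x Numeric expression vector (length = genes).
#' @param S Numeric genes x k signature matrix, k >= 2.
#' @return List: `fractions` (named, >= 0, sums to 1), `residual_norm`
#'   (`|| x - S f ||_2`), `non_unique` flag.
#' @export
solve_simplex_qp <- function(x, S) {
  S <- as.matrix(S)
  if (length(x) != nrow(S)) stop_config("x and S disagree on gene count")
  k <- ncol(S)
  if (k < 2) stop_config("need k >= 2 signatures")

  # collapse exactly duplicated columns (non-unique optimum otherwise)
  key <- apply(S, 2, paste, collapse = "\r")
  grp <- match(key, key)
  non_unique <- any(duplicated(grp))
  uniq <- which(!duplicated(grp))
  Su <- S[, uniq, drop = FALSE]
  ku <- ncol(Su)

  G <- crossprod(Su)                # ku x ku
  b <- crossprod(Su, x)             # ku
  tol <- 1e-10

  solve_support <- function(free) {
    nf <- length(free)
    A <- rbind(cbind(2 * G[free, free, drop = FALSE], rep(1, nf)),
               c(rep(1, nf), 0))
    rhs <- c(2 * b[free], 1)
    sol <- tryCatch(solve(A, rhs),
                    error = function(e) as.vector(MASS::ginv(A) %*% rhs))
    sol[seq_len(nf)]
  }

  if (ku == 1) {
    f_u <- 1
  } else {
    free <- seq_len(ku)
    f_u <- rep(0, ku)
    for (it in seq_len(10 * ku + 10)) {
      fs <- solve_support(free)
      while (min(fs) < -tol) {
        drop_i <- free[which.min(fs)]
        free <- setdiff(free, drop_i)
        if (length(free) == 1L) { fs <- 1; break }
        fs <- solve_support(free)
      }
      f_u[] <- 0
      f_u[free] <- pmax(fs, 0)
      f_u <- f_u / sum(f_u)
      # KKT check for the components held at zero: gradient of the
      # Lagrangian must be non-negative there relative to the free level
      grad <- 2 * (G %*% f_u - b)
      mu <- mean(grad[free])
      zero <- setdiff(seq_len(ku), free)
      if (!length(zero)) break
      viol <- zero[grad[zero] < mu - 1e-9 * max(1, abs(mu))]
      if (!length(viol)) break
      free <- sort(c(free, viol[which.min(grad[viol])]))
    }
  }

  # expand back over duplicates, splitting each group's mass evenly
  fractions <- numeric(k)
  for (j in seq_len(ku)) {
    members <- which(grp == grp[uniq[j]])
    fractions[members] <- f_u[j] / length(members)
  }
  names(fractions) <- colnames(S)
  resid <- x - S %*% fractions
  list(fractions = fractions,
       residual_norm = sqrt(sum(resid^2)),
       non_unique = non_unique)
}

#' Fractional identity of every cell against a signature set
#'
#' Deconvolution runs on the genes shared between matrix and signatures —
#' the whole transcriptome by default, with optional subsetting to a gene
#' list. Matching is by gene id, never by position. Expression must be
#' linear FPKM (a `log2 = TRUE` escape hatch exists for sensitivity
#' analysis).
#'
#' @param x An `expression_matrix` with unit `"fpkm"` (or `"log2fpkm"` with
#'   `log2 = TRUE`).
#' @param signatures A `signature_set`.
#' @param genes Optional gene subset (ids); default the full intersection.
#' @param log2 Deconvolve on log2 values instead of linear (not the default).
#' @param min_genes Minimum usable gene intersection (default 50).
#' @return A `fraction_profiles` object: data.frame with `cell_id`, one
#'   fraction column per state, `residual_norm`, `n_genes_used`,
#'   `non_unique`; attribute `states`.
#' @export
fractional_identity <- function(x, signatures, genes = NULL, log2 = FALSE,
                                min_genes = 50) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(signatures, "signature_set"))
  want_unit <- if (log2) "log2fpkm" else "fpkm"
  if (x$unit != want_unit) {
    stop_config("fractional_identity needs ", want_unit, " input, got ",
                x$unit)
  }
  shared <- intersect(x$gene_ids, signatures$gene_ids)
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < min_genes) {
    stop_config("only ", length(shared), " genes shared with signatures (< ",
                min_genes, ")")
  }
  V <- x$values[match(shared, x$gene_ids), , drop = FALSE]
  S <- signatures$profiles[match(shared, signatures$gene_ids), , drop = FALSE]
  if (log2) S <- log2(S + 1)

  n <- ncol(V)
  k <- ncol(S)
  fr <- matrix(NA_real_, n, k, dimnames = list(NULL, colnames(S)))
  resid <- numeric(n)
  nonu <- logical(n)
  for (i in seq_len(n)) {
    sol <- solve_simplex_qp(V[, i], S)
    fr[i, ] <- sol$fractions
    resid[i] <- sol$residual_norm
    nonu[i] <- sol$non_unique
  }
  out <- data.frame(cell_id = x$cell_ids, fr, residual_norm = resid,
                    n_genes_used = length(shared), non_unique = nonu,
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(out, states = colnames(S),
            class = c("fraction_profiles", "data.frame"))
}

# data.frame subsetting drops custom attributes; recover the state columns
# from the column layout when the attribute is gone.
profile_states <- function(profiles) {
  st <- attr(profiles, "states")
  if (!is.null(st)) return(st)
  setdiff(names(profiles),
          c("cell_id", "residual_norm", "n_genes_used", "non_unique"))
}

#' @export
print.fraction_profiles <- function(x, ...) {
  st <- profile_states(x)
  cat(sprintf("fraction_profiles: %d cells x %d states (%s); %d genes used\n",
              nrow(x), length(st), paste(st, collapse = ", "),
              x$n_genes_used[1]))
  invisible(x)
}

#' Quartile summary of fractions by group
#'
#' The box-and-whisker numbers behind per-group similarity plots: for each
#' group x signature, the minimum, lower quartile, median, upper quartile
#' and maximum of the per-cell fractions (quartiles by R's default type 7).
#' Cells with an empty/NA group label are omitted with a warning.
#'
#' @param profiles A `fraction_profiles` object.
#' @param grouping Character/factor group label per cell (same order).
#' @return Data.frame: `group`, `state`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
similarity_summary <- function(profiles, grouping) {
  stopifnot(inherits(profiles, "fraction_profiles"),
            length(grouping) == nrow(profiles))
  states <- profile_states(profiles)
  grouping <- as.character(grouping)
  keep <- !is.na(grouping) & grouping != ""
  if (!all(keep)) {
    warning(sum(!keep), " cells without a group label omitted")
    profiles <- profiles[keep, , drop = FALSE]
    grouping <- grouping[keep]
  }
  out <- list()
  for (g in sort(unique(grouping))) {
    rows <- profiles[grouping == g, , drop = FALSE]
    for (s in states) {
      v <- rows[[s]]
      q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
      out[[length(out) + 1L]] <- data.frame(
        group = g, state = s, n = length(v),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
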