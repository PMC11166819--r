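`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

assert_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_config(field, "must be a single number in [0, 1]")
  invisible(x)
}

assert_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  invisible(x)
}

assert_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x))
    stop_config(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

#' Shift an array by an integer offset
#'
#' Translates a 2D matrix by `(dy, dx)` voxels. Voxels shifted in from
#' outside the grid are filled with `fill`, or with replicated edge values
#' when `fill = "edge"`.
#'
#' @param m numeric matrix.
#' @param dy,dx integer row/column offsets (content moves down/right for
#'   positive values).
#' @param fill fill value for exposed voxels, or `"edge"` for edge
#'   replication.
#' @return matrix of the same dimensions.
#' @keywords internal
shift_matrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  if (identical(fill, "edge")) {
    src_r <- pmin(pmax(src_r, 1L), nr)
    src_c <- pmin(pmax(src_c, 1L), nc)
    return(m[src_r, src_c, drop = FALSE])
  }
  out <- matrix(fill, nr, nc)
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Neighbourhood offset tables for connected-component labelling.
offsets_2d8 <- function() {
  o <- expand.grid(dy = -1:1, dx = -1:1)
  o[!(o$dy == 0 & o$dx == 0), , drop = FALSE]
}

#' Label connected components of a binary image
#'
#' Iterative minimum-label propagation over an explicit neighbourhood:
#' 8-connected in-plane for 2D masks, 6-connected for 3D masks. Components
#' are relabelled `1..n` in first-voxel order.
#'
#' @param mask logical matrix or 3D array.
#' @return integer array of the same shape; 0 outside the mask.
#' @keywords internal
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  lab[idx] <- seq_along(idx)
  shift_lab <- if (length(dm) == 2L) {
    offs <- offsets_2d8()
    function(l) {
      lapply(seq_len(nrow(offs)), function(i)
        shift_matrix(l, offs$dy[i], offs$dx[i], fill = 0L))
    }
  } else {
    function(l) {
      out <- list()
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        s <- array(0L, dm)
        n <- dm[ax]
        src <- seq_len(n) - dd
        ok <- src >= 1L & src <= n
        ix_to <- lapply(dm, seq_len); ix_from <- lapply(dm, seq_len)
        ix_to[[ax]] <- which(ok); ix_from[[ax]] <- src[ok]
        s <- do.call(`[<-`, c(list(s), ix_to,
                              list(do.call(`[`, c(list(l), ix_from)))))
        out[[length(out) + 1L]] <- s
      }
      out
    }
  }
  repeat {
    nb <- shift_lab(lab)
    new <- lab
    for (s in nb) {
      take <- mask & s > 0L & (new == 0L | s < new)
      new[take] <- s[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  u <- unique(lab[idx])
  lab[idx] <- match(lab[idx], u)
  lab
}
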