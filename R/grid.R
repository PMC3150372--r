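#' Build a parameter grid for inference
#'
#' Lays a regular grid over the free parameters of a model specification
#' (the Cartesian product of per-axis value sequences between the spec's
#' prior bounds) and places a uniform prior on it. The posterior engine,
#' the entropy and the Bayes factors all operate on this finite set of
#' sample parameter values. Axis values are linearly spaced;
#' `neighbour_count` axes are rounded to unique integers.
#'
#' @param spec a [model_spec()].
#' @param resolution points per axis: a single count, or a named vector /
#'   list with one count per free parameter. Every axis needs at least 2
#'   points.
#' @param fixed_update_prob the update probability assumed by the
#'   likelihood when the spec does not infer it (almost always 1).
#' @return an object of class `param_grid`.
#' @export
#' @examples
#' g <- make_grid(model_spec(), resolution = 5)
#' grid_size(g) # 5^5
make_grid <- function(spec, resolution = 9, fixed_update_prob = 1) {
  free <- names(spec$parameter_axes)
  if (is.list(resolution)) resolution <- unlist(resolution)
  if (is.null(names(resolution))) {
    res <- setNames(rep(resolution[[1]], length(free)), free)
  } else {
    res <- setNames(rep(9L, length(free)), free)
    unknown <- setdiff(names(resolution), free)
    if (length(unknown)) {
      abort(paste0("`resolution` names not free parameters: ", paste(unknown, collapse = ", ")))
    }
    res[names(resolution)] <- resolution
  }
  if (any(res < 2)) abort("Every axis needs a resolution of at least 2 points.")
  axes <- list()
  for (nm in free) {
    bb <- spec$parameter_axes[[nm]]
    v <- seq(bb[1], bb[2], length.out = res[[nm]])
    if (nm == "neighbour_count") v <- unique(round(v))
    if (length(v) < 2) abort("`neighbour_count` axis collapsed below 2 distinct integers.")
    axes[[nm]] <- v
  }
  k <- prod(vapply(axes, length, integer(1)))
  structure(
    list(
      axes = axes, spec = spec, fixed_update_prob = fixed_update_prob,
      log_prior = rep(-base::log(k), k)
    ),
    class = "param_grid"
  )
}

#' @rdname make_grid
#' @param grid a `param_grid`.
#' @export
grid_size <- function(grid) {
  prod(vapply(grid$axes, length, integer(1)))
}

#' Grid points as a tibble
#'
#' @param x a `param_grid`.
#' @param ... unused.
#' @return a tibble with one row per grid point (first axis varying
#'   fastest) and one column per free parameter, plus `log_prior`.
#' @export
tidy.param_grid <- function(x, ...) {
  out <- tibble::as_tibble(expand.grid(x$axes, KEEP.OUT.ATTRS = FALSE))
  out$log_prior <- x$log_prior
  out
}

#' @export
print.param_grid <- function(x, ...) {
  cat("<param_grid> ", grid_size(x), " points\n", sep = "")
  for (nm in names(x$axes)) {
    v <- x$axes[[nm]]
    cat(sprintf(
      "  %-18s %d points in [%g, %g]\n", nm, length(v), min(v), max(v)
    ))
  }
  invisible(x)
}

## ---- vectorised grid likelihood ------------------------------------------
## Log-likelihood of one observed transition at EVERY grid point, in grid
## order (first axis fastest). Exploits the factorisation of the model:
## neighbourhoods depend only on (radius-or-count, blind angle), predicted
## headings additionally on the force weights, and the noise density on
## (sigma, update probability). Absent axes enter as singleton dimensions,
## so the output ordering matches expand.grid() over the present axes.
grid_step_loglik <- function(st, new_headings, grid) {
  spec <- grid$spec
  axes <- grid$axes
  n <- length(st$x)
  geom <- st$geom
  ux <- cos(st$heading)
  uy <- sin(st$heading)

  att_vals <- axes$attraction_weight %||% 0
  ali_vals <- axes$alignment_weight %||% 0
  geometric <- spec$neighbourhood == "geometric"
  r_vals <- if (geometric) axes$interaction_radius else axes$neighbour_count
  b_vals <- axes$blind_angle
  sig_vals <- axes$noise_sd
  p_vals <- axes$update_prob %||% grid$fixed_update_prob
  has_p_axis <- !is.null(axes$update_prob)

  n_att <- length(att_vals)
  n_ali <- length(ali_vals)
  n_r <- length(r_vals)
  n_b <- length(b_vals)
  n_sig <- length(sig_vals)
  n_p <- length(p_vals)
  n_rb <- n_r * n_b

  ## social-force sums per (radius-or-count, blind) combination
  Ax <- Ay <- Cx <- Cy <- matrix(0, n, n_rb)
  for (ib in seq_len(n_b)) {
    vis <- abs(geom$rel_bearing) <= pi - b_vals[ib] / 2
    diag(vis) <- FALSE
    if (geometric) {
      for (ir in seq_len(n_r)) {
        m <- vis & geom$dist <= r_vals[ir]
        col <- (ib - 1L) * n_r + ir
        Ax[, col] <- m %*% ux
        Ay[, col] <- m %*% uy
        Cx[, col] <- rowSums(m * geom$dx)
        Cy[, col] <- rowSums(m * geom$dy)
      }
    } else {
      for (i in seq_len(n)) {
        d <- geom$dist[i, ]
        d[!vis[i, ]] <- Inf
        ord <- order(d, seq_len(n))
        nvis <- sum(is.finite(d))
        cux <- cumsum(ux[ord])
        cuy <- cumsum(uy[ord])
        cdx <- cumsum(geom$dx[i, ord])
        cdy <- cumsum(geom$dy[i, ord])
        for (ir in seq_len(n_r)) {
          take <- min(r_vals[ir], nvis)
          if (take > 0) {
            col <- (ib - 1L) * n_r + ir
            Ax[i, col] <- cux[take]
            Ay[i, col] <- cuy[take]
            Cx[i, col] <- cdx[take]
            Cy[i, col] <- cdy[take]
          }
        }
      }
    }
  }
  a <- unitize_rows(as.numeric(Ax), as.numeric(Ay))
  cc <- unitize_rows(as.numeric(Cx), as.numeric(Cy))

  ## predicted headings per (rb, weight) combination
  w_att <- rep(att_vals, times = n_ali)
  w_ali <- rep(ali_vals, each = n_att)
  uxr <- rep(ux, n_rb)
  uyr <- rep(uy, n_rb)
  X <- outer(a$x, w_ali) + outer(cc$x, w_att) + uxr
  Y <- outer(a$y, w_ali) + outer(cc$y, w_att) + uyr
  pred <- atan2(Y, X)
  degenerate <- X^2 + Y^2 < 1e-24
  if (any(degenerate)) {
    pred[degenerate] <- rep(st$heading, n_rb)[row(pred)[degenerate]]
  }
  delta <- wrap_angle(rep(new_headings, n_rb) - pred)
  delta_keep <- wrap_angle(new_headings - st$heading)

  out <- array(0, c(n_att, n_ali, n_r, n_b, n_sig, n_p))
  pure <- !has_p_axis && grid$fixed_update_prob >= 1
  for (is in seq_len(n_sig)) {
    lw1 <- dwrapnorm(delta, sig_vals[is], log = TRUE)
    if (pure) {
      contribs <- list(lw1)
    } else {
      lw0 <- rep(dwrapnorm(delta_keep, sig_vals[is], log = TRUE), n_rb)
      m <- pmax(lw1, lw0)
      both_under <- m == -Inf
      m[both_under] <- 0 # avoid -Inf - -Inf = NaN; restored below
      e1 <- exp(lw1 - m)
      e0 <- exp(lw0 - m)
      contribs <- lapply(p_vals, function(p) {
        out_p <- base::log(p * e1 + (1 - p) * e0) + m
        out_p[both_under] <- -Inf
        out_p
      })
    }
    for (ip in seq_along(contribs)) {
      s <- colSums(array(contribs[[ip]], c(n, n_r * n_b * n_att * n_ali)))
      out[, , , , is, ip] <- aperm(array(s, c(n_r, n_b, n_att, n_ali)), c(3, 4, 1, 2))
    }
  }
  as.numeric(out)
}
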