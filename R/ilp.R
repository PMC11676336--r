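# ILP search for minimum-density schemes.
#
# Forward mode: one integer variable x_W in [w] per window W (a vertex of
# B_{w+k-1}) and one binary y_e per edge (= context of length w+k).  The
# scheme must be forward on every edge (x_u <= x_v + 1), and y_e is forced
# to 1 unless x_u = x_v + 1 via two big-M inequalities with M = w (the
# tightest constant given the variable ranges).  Minimizing sum(y) minimizes
# the number of charged contexts, i.e. the density.  Optionally, for every
# pure cycle c of B_{w+k}, the valid cut sum_{e in c} y_e >= ceil(|c|/w) is
# added (each vertex of B_{w+k} *is* an edge of B_{w+k-1}); the cuts restate
# the necklace lower bound and only prune the search.
#
# Local mode: contexts have length 2w+k-2.  The window choice is one-hot
# encoded: binaries b_{W,a} with sum_a b_{W,a} = 1 say that window W selects
# offset a.  A context C is uncharged exactly when some preceding window i
# selects the same absolute position as the last window, i.e. when
# x_{W_i} = x_last + (w-1-i); so for every a in [w] the row
#   y_C >= b_{last,a} - sum_{i} b_{W_i, a+w-1-i}
# forces y_C = 1 on charged contexts and lets it drop to 0 otherwise.  This
# avoids big-M constants entirely and gives a much stronger LP relaxation
# than an integer-x encoding.  No forwardness rows: local schemes are
# unconstrained.  Because the charged contexts of any local scheme form a
# (w, 2w+k-2)-UHS, two families of valid rows are added by default: pure-
# cycle cuts (sum of y over a cycle of B_{2w+k-2} >= ceil(|c|/w)) and walk
# covers (every w consecutive contexts contain a charged one).  They never
# change the optimum -- the true charged indicator satisfies both -- but
# they are what makes the relaxation strong enough to solve in seconds.
#
# The model layer is solver-agnostic (plain sparse triplets); the bundled
# backend solves with HiGHS through SciPy in a Python subprocess.

.INF <- 1e30

.new_model <- function(mode, sigma, w, k, nvar, obj, integrality, lb, ub,
                       ai, aj, ax, row_lb, row_ub, meta = list()) {
  structure(c(list(mode = mode, sigma = sigma, w = w, k = k,
                   nvar = nvar, obj = obj, integrality = integrality,
                   lb = lb, ub = ub,
                   ai = ai, aj = aj, ax = ax,
                   nrow = length(row_lb), row_lb = row_lb, row_ub = row_ub),
              meta),
            class = "ilp_model")
}

#' @export
print.ilp_model <- function(x, ...) {
  cat(sprintf("<ilp_model %s> sigma=%d w=%d k=%d: %d vars, %d rows, %d nonzeros\n",
              x$mode, x$sigma, x$w, x$k, x$nvar, x$nrow, length(x$ax)))
  invisible(x)
}

#' Build the ILP for minimum-density forward schemes
#'
#' @param sigma alphabet size.
#' @param w window guarantee.
#' @param k k-mer length.
#' @param with_cuts add one covering cut per pure cycle of B_{w+k}
#'   (default TRUE; the cuts never change the optimum).
#' @param budget refuse when sigma^(w+k) exceeds this.
#' @return an `ilp_model`; variables are the sigma^(w+k-1) window indices
#'   followed by the sigma^(w+k) charged-edge indicators.
#' @export
build_forward_ilp <- function(sigma, w, k, with_cuts = TRUE, budget = 1e6) {
  stopifnot(sigma >= 2, w >= 1, k >= 1)
  ny <- sigma^(w + k)
  .enum_budget_check(ny, budget, "build_forward_ilp")
  nx <- sigma^(w + k - 1)
  e <- 0:(ny - 1)
  u <- e %/% sigma   # head window of the edge
  v <- e %% nx       # tail window
  yi <- nx + e       # 0-based column of y_e

  # rows: [forward | charge+ | charge-] per edge, then cycle cuts
  ai <- c(e, e,                       # forward: x_u - x_v <= 1
          ny + e, ny + e, ny + e,     # x_u - x_v - w*y <= 1
          2 * ny + e, 2 * ny + e, 2 * ny + e) # x_v - x_u - w*y <= -1
  aj <- c(u, v,
          u, v, yi,
          u, v, yi)
  ax <- c(rep(1, ny), rep(-1, ny),
          rep(1, ny), rep(-1, ny), rep(-w, ny),
          rep(-1, ny), rep(1, ny), rep(-w, ny))
  row_lb <- rep(-.INF, 3 * ny)
  row_ub <- c(rep(1, ny), rep(1, ny), rep(-1, ny))

  n_cuts <- 0L
  if (with_cuts) {
    cycles <- enumerate_pure_cycles(sigma, w + k, budget = budget)
    n_cuts <- length(cycles)
    r0 <- 3 * ny
    for (cy in cycles) {
      ai <- c(ai, rep(r0, cy$length))
      aj <- c(aj, nx + cy$vertices)
      ax <- c(ax, rep(1, cy$length))
      row_lb <- c(row_lb, ceiling(cy$length / w))
      row_ub <- c(row_ub, .INF)
      r0 <- r0 + 1L
    }
  }

  .new_model("forward", sigma, w, k,
             nvar = nx + ny,
             obj = c(rep(0, nx), rep(1, ny)),
             integrality = rep(1L, nx + ny),
             lb = rep(0, nx + ny),
             ub = c(rep(w - 1, nx), rep(1, ny)),
             ai = ai, aj = aj, ax = ax,
             row_lb = row_lb, row_ub = row_ub,
             meta = list(nx = nx, ny = ny, with_cuts = with_cuts, n_cuts = n_cuts))
}

#' Build the ILP for minimum-density local schemes
#'
#' @inheritParams build_forward_ilp
#' @param budget refuse when sigma^(2w+k-2) exceeds this.
#' @param with_cuts add the UHS-derived pure-cycle cuts and walk covers on
#'   the charged indicators (default TRUE; they never change the optimum
#'   but are essential for solve speed).
#' @return an `ilp_model`; variables are the one-hot window-choice binaries
#'   `b[W, a]` (window-major, `sigma^(w+k-1) * w` of them) followed by one
#'   charged indicator per context of length 2w+k-2.
#' @export
build_local_ilp <- function(sigma, w, k, with_cuts = TRUE, budget = 1e6) {
  stopifnot(sigma >= 2, w >= 2, k >= 1)
  ell <- 2L * w + k - 2L
  nc <- sigma^ell
  .enum_budget_check(nc, budget, "build_local_ilp")
  nx <- sigma^(w + k - 1)
  nb <- nx * w              # b columns: W * w + a
  ctx <- 0:(nc - 1)
  wlast <- (ctx %/% sigma^(ell - (w - 1) - (w + k - 1))) %% nx
  woff <- lapply(0:(w - 2L), function(i) (ctx %/% sigma^(ell - i - (w + k - 1))) %% nx)

  # one-hot rows: sum_a b[W,a] = 1
  ai <- rep(0:(nx - 1), each = w)
  aj <- as.vector(vapply(0:(nx - 1), function(W) W * w + 0:(w - 1), numeric(w)))
  ax <- rep(1, nx * w)
  row_lb <- rep(1, nx)
  row_ub <- rep(1, nx)

  # per context and a: y_C - b[last,a] + sum_i b[W_i, a+w-1-i] >= 0
  r0 <- nx
  for (a in 0:(w - 1L)) {
    rows <- r0 + ctx
    ai <- c(ai, rows, rows)
    aj <- c(aj, nb + ctx, wlast * w + a)
    ax <- c(ax, rep(1, nc), rep(-1, nc))
    for (i in 0:(w - 2L)) {
      ap <- a + (w - 1L) - i
      if (ap >= w) next  # that offset cannot land on the same position
      ai <- c(ai, rows)
      aj <- c(aj, woff[[i + 1L]] * w + ap)
      ax <- c(ax, rep(1, nc))
    }
    row_lb <- c(row_lb, rep(0, nc))
    row_ub <- c(row_ub, rep(.INF, nc))
    r0 <- r0 + nc
  }

  if (with_cuts) {
    # pure-cycle cuts on the order-ell De Bruijn graph
    cycles <- enumerate_pure_cycles(sigma, ell, budget = budget)
    for (cy in cycles) {
      ai <- c(ai, rep(r0, cy$length))
      aj <- c(aj, nb + cy$vertices)
      ax <- c(ax, rep(1, cy$length))
      row_lb <- c(row_lb, ceiling(cy$length / w))
      row_ub <- c(row_ub, .INF)
      r0 <- r0 + 1L
    }
    # walk covers: every w consecutive contexts contain a charged one
    ns <- sigma^(ell + w - 1)
    .enum_budget_check(ns, budget, "build_local_ilp (walk covers)")
    s <- 0:(ns - 1)
    for (i in 0:(w - 1L)) {
      ai <- c(ai, r0 + s)
      aj <- c(aj, nb + (s %/% sigma^(w - 1 - i)) %% nc)
      ax <- c(ax, rep(1, ns))
    }
    row_lb <- c(row_lb, rep(1, ns))
    row_ub <- c(row_ub, rep(.INF, ns))
    r0 <- r0 + ns
  }

  nvar <- nb + nc
  .new_model("local", sigma, w, k,
             nvar = nvar,
             obj = c(rep(0, nb), rep(1, nc)),
             integrality = rep(1L, nvar),
             lb = rep(0, nvar),
             ub = rep(1, nvar),
             ai = ai, aj = aj, ax = ax,
             row_lb = row_lb, row_ub = row_ub,
             meta = list(nx = nx, nb = nb, nc = nc))
}

# locate the bundled SciPy/HiGHS backend script
.milp_backend <- function() {
  script <- system.file("python", "milp_solve.py", package = "minidens")
  if (!nzchar(script)) stop("bundled MILP backend script not found")
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) stop("no `python` interpreter with scipy on PATH; the MILP backend needs one")
  list(python = python, script = script)
}

#' Solve an `ilp_model` with the bundled MILP backend
#'
#' Serializes the model, solves it with HiGHS (via SciPy) in a subprocess,
#' and returns the raw solution: `status` in {optimal, timeout, infeasible,
#' unbounded, failed}, `objective`, and the variable vector `x`.
#'
#' @param model an `ilp_model`.
#' @param time_limit seconds, or NULL for no limit.
#' @export
milp_solve <- function(model, time_limit = NULL) {
  stopifnot(inherits(model, "ilp_model"))
  be <- .milp_backend()
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  payload <- list(nvar = model$nvar, obj = model$obj,
                  integrality = model$integrality,
                  lb = model$lb, ub = model$ub,
                  nrow = model$nrow, ai = model$ai, aj = model$aj, ax = model$ax,
                  row_lb = model$row_lb, row_ub = model$row_ub,
                  time_limit = time_limit)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA, null = "null")
  rc <- system2(be$python, c(be$script, fin, fout), stdout = TRUE, stderr = TRUE)
  status <- attr(rc, "status")
  if (!is.null(status) && status != 0) {
    stop("MILP backend failed:\n", paste(rc, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  res$status <- switch(as.character(res$status),
                       "0" = "optimal", "1" = "timeout", "2" = "infeasible",
                       "3" = "unbounded", "failed")
  res
}

.new_ilp_solution <- function(status, objective, sigma, w, k, ell, scheme, mode) {
  structure(list(status = status, objective = objective,
                 density = objective / sigma^ell,
                 num = objective, den = sigma^ell,
                 scheme = scheme, mode = mode,
                 sigma = sigma, w = w, k = k),
            class = "ilp_solution")
}

#' @export
print.ilp_solution <- function(x, ...) {
  cat(sprintf("<ilp_solution %s> sigma=%d w=%d k=%d: status=%s, %g charged contexts, density %g/%g = %.6f\n",
              x$mode, x$sigma, x$w, x$k, x$status, x$objective, x$num, x$den, x$density))
  invisible(x)
}

#' Minimum-density forward scheme by ILP
#'
#' Builds and solves the forward-scheme ILP, extracts the window table, and
#' re-verifies the solution independently: the returned scheme is checked to
#' be forward and its exact charged-context count recomputed by enumeration
#' must equal the solver objective.
#'
#' @inheritParams build_forward_ilp
#' @param time_limit seconds, or NULL.
#' @return an `ilp_solution` carrying a [table_scheme].
#' @export
solve_forward <- function(sigma, w, k, with_cuts = TRUE, time_limit = NULL,
                          budget = 1e6) {
  model <- build_forward_ilp(sigma, w, k, with_cuts = with_cuts, budget = budget)
  res <- milp_solve(model, time_limit = time_limit)
  if (is.null(res$x) || length(res$x) == 0) {
    stop("forward ILP returned no incumbent (status: ", res$status, ")")
  }
  xs <- round(res$x)
  tab <- xs[seq_len(model$nx)]
  obj <- sum(xs[model$nx + seq_len(model$ny)])
  scheme <- table_scheme(w, k, sigma, tab)
  chk <- is_forward(scheme, budget = budget)
  if (!chk$forward) stop("ILP solution violates forwardness; model is inconsistent")
  dens <- exact_density(scheme, "forward", budget = budget)
  if (dens$charged != obj) {
    stop(sprintf("solver objective %g disagrees with recomputed charged count %g", obj, dens$charged))
  }
  .new_ilp_solution(res$status, obj, sigma, w, k, w + k, scheme, "forward")
}

# local-mode charged count of a window table, vectorized over all contexts
.local_charged_count <- function(tab, sigma, w, k) {
  ell <- 2L * w + k - 2L
  nc <- sigma^ell
  nx <- sigma^(w + k - 1)
  ctx <- 0:(nc - 1)
  xlast <- tab[(ctx %/% sigma^(ell - (w - 1) - (w + k - 1))) %% nx + 1L] + (w - 1L)
  unch <- rep(FALSE, nc)
  for (i in 0:(w - 2L)) {
    wi <- (ctx %/% sigma^(ell - i - (w + k - 1))) %% nx
    unch <- unch | (tab[wi + 1L] + i == xlast)
  }
  nc - sum(unch)
}

# seeded simulated-annealing search over window tables for the local
# objective; used as the primal stage of solve_local
.anneal_local <- function(tab0, sigma, w, k, iters, restarts, seed) {
  nx <- sigma^(w + k - 1)
  best_tab <- tab0
  best <- .local_charged_count(tab0, sigma, w, k)
  .with_seed(seed, {
    for (r in seq_len(restarts)) {
      tab <- if (r == 1L) tab0 else sample.int(w, nx, replace = TRUE) - 1L
      cur <- .local_charged_count(tab, sigma, w, k)
      temp <- 3
      for (it in seq_len(iters)) {
        temp <- max(0.01, temp * 0.9995)
        wi <- sample.int(nx, 1L)
        a <- sample.int(w, 1L) - 1L
        if (tab[wi] == a) next
        old <- tab[wi]
        tab[wi] <- a
        new <- .local_charged_count(tab, sigma, w, k)
        if (new <= cur || stats::runif(1) < exp((cur - new) / temp)) {
          cur <- new
        } else {
          tab[wi] <- old
        }
      }
      if (cur < best) { best <- cur; best_tab <- tab }
    }
  })
  list(tab = best_tab, objective = best)
}

#' Minimum-density local scheme by ILP with an annealing primal stage
#'
#' Local-scheme instances are much harder to certify than forward ones: the
#' LP relaxation bounds the charged count only through the covering rows,
#' far below the true optimum.  This routine therefore (1) solves the fast
#' forward ILP and improves its table by seeded simulated annealing under
#' the exact local objective, then (2) asks the local ILP to certify the
#' incumbent by proving that one fewer charged context is infeasible,
#' within `time_limit` seconds.  If certification succeeds the status is
#' `"optimal"`; if the solver finds a strictly better scheme it is adopted;
#' otherwise the incumbent is returned with status `"feasible"` and the
#' solver's dual bound in `$dual_bound`.  The returned table is always
#' re-verified by local-mode charged-context enumeration.
#'
#' @inheritParams build_local_ilp
#' @param time_limit seconds allowed for the certification solve.
#' @param anneal_iters,restarts,seed annealing schedule (deterministic for a
#'   fixed seed).
#' @export
solve_local <- function(sigma, w, k, time_limit = 60, budget = 1e6,
                        anneal_iters = 20000, restarts = 4, seed = 1) {
  fwd <- solve_forward(sigma, w, k, budget = budget)
  prim <- .anneal_local(fwd$scheme$table, sigma, w, k,
                        iters = anneal_iters, restarts = restarts, seed = seed)
  tab <- prim$tab
  obj <- prim$objective
  status <- "feasible"
  dual_bound <- NA_real_

  model <- build_local_ilp(sigma, w, k, budget = budget)
  # objective cutoff: any strictly better scheme has sum(y) <= obj - 1
  nc <- model$nc
  model$ai <- c(model$ai, rep(model$nrow, nc))
  model$aj <- c(model$aj, model$nb + 0:(nc - 1))
  model$ax <- c(model$ax, rep(1, nc))
  model$row_lb <- c(model$row_lb, -.INF)
  model$row_ub <- c(model$row_ub, obj - 1)
  model$nrow <- model$nrow + 1L
  model$integrality[model$nb + seq_len(nc)] <- 0L  # y follows from integral b

  res <- milp_solve(model, time_limit = time_limit)
  if (res$status == "infeasible") {
    status <- "optimal"  # nothing below the incumbent exists
  } else if (!is.null(res$x) && length(res$x) > 0) {
    xs <- round(res$x)
    b <- matrix(xs[seq_len(model$nb)], nrow = w)
    tab2 <- apply(b, 2, which.max) - 1L
    obj2 <- .local_charged_count(tab2, sigma, w, k)
    if (obj2 < obj) { tab <- tab2; obj <- obj2 }
    if (res$status == "optimal") status <- "optimal"
  }
  if (status != "optimal" && !is.null(res$mip_dual_bound)) {
    dual_bound <- as.numeric(res$mip_dual_bound)
  }

  scheme <- table_scheme(w, k, sigma, tab)
  dens <- exact_density(scheme, "local", budget = budget)
  if (dens$charged != obj) {
    stop(sprintf("annealing objective %g disagrees with recomputed charged count %g", obj, dens$charged))
  }
  out <- .new_ilp_solution(status, obj, sigma, w, k, 2 * w + k - 2, scheme, "local")
  out$dual_bound <- dual_bound
  out
}
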