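#' Transition-path-theory analysis of a Markov model
#'
#' Computes, for a reversible basin-level Markov model, the forward
#' committor `q+` (probability of reaching the product set before
#' returning to the source), the backward committor `q-` (from the
#' time-reversed chain; equal to `1 - q+` under detailed balance), the
#' effective reactive flux `f_ij = pi_i q-_i T_ij q+_j` (i != j), the net
#' flux `f+_ij = max(0, f_ij - f_ji)`, and the total reactive flux
#' `F = sum_j f+(source -> j)`. Fluxes are per (unitless) lag step and are
#' meaningful for comparison only, never as absolute rates.
#'
#' Committors are obtained by a direct linear solve of the harmonic system
#' (`q+_i = sum_j T_ij q+_j` on intermediates, 0 on the source, 1 on
#' targets), falling back to damped fixed-point iteration if the system is
#' numerically singular.
#'
#' @param model a `markov_model`.
#' @param source source state (id or name), typically `"solvent"`.
#' @param targets product state ids; must not contain the source.
#' @param pi optional stationary distribution; defaults to `Z / sum(Z)`,
#'   which is exact for landscape-built models.
#' @return Object of class `tpt_result`: `q_plus`, `q_minus`, `flux`
#'   (effective), `net_flux`, `total_flux`, `source`, `targets`, `pi`.
#' @export
tpt_analysis <- function(model, source, targets, pi = NULL) {
  stopifnot(inherits(model, "markov_model"))
  tm <- model$T
  n <- nrow(tm)
  src <- match(as.character(source), model$states)
  tgt <- match(as.character(targets), model$states)
  if (anyNA(src) || anyNA(tgt)) stop("unknown state id in source/targets")
  if (src %in% tgt) stop("source must not be a target state")
  if (is.null(pi)) pi <- model$Z / sum(model$Z)
  pi <- as.numeric(pi)

  gr <- igraph::graph_from_adjacency_matrix(tm > 0, mode = "directed")
  reach <- igraph::subcomponent(gr, src, mode = "out")
  if (!any(tgt %in% as.integer(reach))) {
    message("targets unreachable from source after cutoff; total flux = 0")
    qp <- rep(0, n); qp[tgt] <- 1
    qm <- rep(0, n); qm[src] <- 1
    zero <- matrix(0, n, n, dimnames = dimnames(tm))
    return(structure(list(q_plus = stats::setNames(qp, model$states),
                          q_minus = stats::setNames(qm, model$states),
                          flux = zero, net_flux = zero, total_flux = 0,
                          source = model$states[src],
                          targets = model$states[tgt],
                          pi = stats::setNames(pi, model$states)),
                     class = "tpt_result"))
  }

  qp <- solve_committor(tm, boundary0 = src, boundary1 = tgt)
  ## backward committor on the time-reversed chain
  trev <- t(tm * pi) / pi
  qm <- solve_committor(trev, boundary0 = tgt, boundary1 = src)

  f <- (pi * qm) * tm * rep(qp, each = n)
  diag(f) <- 0
  fplus <- pmax(f - t(f), 0)
  dimnames(f) <- dimnames(fplus) <- dimnames(tm)
  total <- sum(fplus[src, ])
  structure(list(q_plus = stats::setNames(qp, model$states),
                 q_minus = stats::setNames(qm, model$states),
                 flux = f, net_flux = fplus, total_flux = total,
                 source = model$states[src], targets = model$states[tgt],
                 pi = stats::setNames(pi, model$states)),
            class = "tpt_result")
}

## committor with value 0 on boundary0, 1 on boundary1, harmonic elsewhere
solve_committor <- function(tm, boundary0, boundary1) {
  n <- nrow(tm)
  q <- rep(NA_real_, n)
  q[boundary0] <- 0
  q[boundary1] <- 1
  inter <- which(is.na(q))
  if (!length(inter)) return(q)
  a <- diag(length(inter)) - tm[inter, inter, drop = FALSE]
  b <- tm[inter, boundary1, drop = FALSE] %*% rep(1, length(boundary1))
  qi <- tryCatch(as.numeric(solve(a, b)), error = function(e) NULL)
  if (is.null(qi)) {
    ## fixed-point iteration fallback for singular systems
    qi <- rep(0, length(inter))
    for (it in seq_len(100000L)) {
      qn <- as.numeric(tm[inter, inter, drop = FALSE] %*% qi + b)
      if (max(abs(qn - qi)) < 1e-14) { qi <- qn; break }
      qi <- qn
    }
  }
  q[inter] <- pmin(pmax(qi, 0), 1)
  q
}

#' @export
print.tpt_result <- function(x, ...) {
  cat(sprintf("tpt_result: %s -> {%s}, total net flux %.4g per step\n",
              x$source, paste(x$targets, collapse = ", "), x$total_flux))
  invisible(x)
}

#' Bottleneck decomposition into ranked reactive pathways
#'
#' Decomposes the net-flux network by repeatedly extracting the
#' maximum-bottleneck source-to-target path (widest-path search) and
#' subtracting its bottleneck flux from every edge along it, until the
#' remaining flux is exhausted. Pathways with flux of at least
#' `fraction` times the strongest pathway's flux are retained and grouped
#' by the product basin they end in.
#'
#' @param result a [tpt_analysis()] result with `total_flux > 0`.
#' @param fraction retention threshold relative to the strongest pathway.
#'   Default 0.5.
#' @param max_paths safety cap on the number of extracted paths.
#' @return Object of class `pathway_set`: `pathways` (data.frame: rank,
#'   flux, product, share of total flux, state sequence), `paths` (list of
#'   state-id vectors), `groups` (per-product-basin flux sums and
#'   percentages via [pathway_percentages()]), `total_flux`.
#' @export
top_pathways <- function(result, fraction = 0.5, max_paths = 1000L) {
  stopifnot(inherits(result, "tpt_result"))
  if (result$total_flux <= 0) stop("total flux is zero; no pathways")
  states <- names(result$q_plus)
  src <- match(result$source, states)
  tgt <- match(result$targets, states)
  cap <- result$net_flux
  tol <- 1e-14 * result$total_flux
  paths <- list(); fluxes <- numeric(0)
  repeat {
    wp <- widest_path(cap, src, tgt)
    if (is.null(wp) || wp$width <= tol) break
    for (k in seq_len(length(wp$path) - 1L))
      cap[wp$path[k], wp$path[k + 1L]] <- cap[wp$path[k], wp$path[k + 1L]] - wp$width
    paths[[length(paths) + 1L]] <- wp$path
    fluxes <- c(fluxes, wp$width)
    if (length(paths) >= max_paths) break
  }
  if (!length(paths)) stop("no source-to-target path in the net flux network")
  keep <- fluxes >= fraction * max(fluxes)
  ord <- order(fluxes, decreasing = TRUE)
  ord <- ord[keep[ord]]
  paths <- paths[ord]; fluxes <- fluxes[ord]
  product <- vapply(paths, function(p) states[p[length(p)]], "")
  pw <- data.frame(rank = seq_along(paths), flux = fluxes, product = product,
                   share_percent = 100 * fluxes / result$total_flux,
                   states = vapply(paths, function(p)
                     paste(states[p], collapse = " -> "), ""))
  gflux <- tapply(fluxes, product, sum)
  groups <- data.frame(product = names(gflux), flux = as.numeric(gflux))
  groups$percent <- pathway_percentages(groups$flux)
  groups <- groups[order(groups$flux, decreasing = TRUE), ]
  rownames(groups) <- NULL
  structure(list(pathways = pw,
                 paths = lapply(paths, function(p) states[p]),
                 groups = groups, total_flux = result$total_flux),
            class = "pathway_set")
}

## maximum-bottleneck (widest) path from src to any target; Dijkstra variant
widest_path <- function(cap, src, tgt) {
  n <- nrow(cap)
  width <- rep(-Inf, n)
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  width[src] <- Inf
  repeat {
    u <- which(!done & width > -Inf)
    if (!length(u)) return(NULL)
    u <- u[which.max(width[u])]
    if (u %in% tgt) break
    done[u] <- TRUE
    nb <- which(cap[u, ] > 0 & !done)
    for (v in nb) {
      w2 <- min(width[u], cap[u, v])
      if (w2 > width[v]) { width[v] <- w2; parent[v] <- u }
    }
  }
  path <- u
  while (!is.na(parent[path[1L]])) path <- c(parent[path[1L]], path)
  if (path[1L] != src) return(NULL)
  list(path = path, width = width[u])
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("pathway_set: %d pathway(s), total flux %.4g\n",
              nrow(x$pathways), x$total_flux))
  print(x$pathways[, c("rank", "flux", "product", "share_percent")])
  invisible(x)
}

#' Percentages of a set of pathway fluxes
#'
#' `100 * f_k / sum(f)`, the per-product-basin share of the summed fluxes;
#' the result always sums to 100.
#'
#' @param fluxes numeric vector of per-pathway (or per-product-basin)
#'   fluxes, all > 0.
#' @return Numeric vector of percentages.
#' @export
pathway_percentages <- function(fluxes) {
  fluxes <- as.numeric(fluxes)
  if (!length(fluxes) || any(!is.finite(fluxes)) || any(fluxes <= 0))
    stop("all fluxes must be finite and > 0")
  100 * fluxes / sum(fluxes)
}

#' Group product basins sharing a reactive network
#'
#' Two product basins are assigned to the same pathway group when the
#' retained pathways ending in them share at least `overlap` of their
#' intermediate states (overlap measured against the smaller intermediate
#' set; basins whose pathways have no intermediates group only with
#' identical empty sets). This is one operationalization of "product basins
#' sharing the same reactive network"; see the methods vignette.
#'
#' @param pathway_set a [top_pathways()] result.
#' @param overlap shared-intermediate fraction threshold. Default 0.5.
#' @return data.frame: product basin, group id.
#' @export
group_product_basins <- function(pathway_set, overlap = 0.5) {
  prods <- unique(pathway_set$pathways$product)
  inter_sets <- lapply(prods, function(p) {
    ps <- pathway_set$paths[pathway_set$pathways$product == p]
    unique(unlist(lapply(ps, function(q) q[-c(1L, length(q))])))
  })
  n <- length(prods)
  adj <- diag(n) > 0
  for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
    sa <- inter_sets[[a]]; sb <- inter_sets[[b]]
    shared <- if (!length(sa) && !length(sb)) 1
      else if (!length(sa) || !length(sb)) 0
      else length(intersect(sa, sb)) / min(length(sa), length(sb))
    adj[a, b] <- adj[b, a] <- shared >= overlap
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  data.frame(product = prods, group = as.integer(comp))
}

#' Write TPT matrices and the pathway report as TSV
#'
#' `write_tpt_result()` writes committors/pi as one table and the net flux
#' matrix as another (state ids as header); `write_pathway_report()` writes
#' the grouped pathway table (pathway group, product basin, flux, percent
#' of summed flux).
#'
#' @param result a [tpt_result][tpt_analysis()].
#' @param prefix output path prefix; `<prefix>_states.tsv` and
#'   `<prefix>_netflux.tsv` are created.
#' @return Written paths, invisibly.
#' @export
write_tpt_result <- function(result, prefix) {
  st <- data.frame(state = names(result$q_plus), pi = result$pi,
                   q_plus = result$q_plus, q_minus = result$q_minus)
  p1 <- paste0(prefix, "_states.tsv")
  utils::write.table(st, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  p2 <- paste0(prefix, "_netflux.tsv")
  utils::write.table(data.frame(state = rownames(result$net_flux),
                                result$net_flux, check.names = FALSE),
                     p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' @param pathways a [pathway_set][top_pathways()].
#' @param groups optional [group_product_basins()] table for group labels.
#' @param path output TSV path.
#' @rdname write_tpt_result
#' @export
write_pathway_report <- function(pathways, path, groups = NULL) {
  g <- pathways$groups
  if (is.null(groups)) {
    g$group <- seq_len(nrow(g))
  } else {
    g$group <- groups$group[match(g$product, groups$product)]
  }
  out <- data.frame(pathway_group = g$group, product_basin = g$product,
                    flux = g$flux, percent_of_sum = g$percent)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
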