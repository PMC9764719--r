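# Directed acyclic graphs for time-varying exposure problems: construction,
# d-separation (reachability / Bayes-ball style), backdoor-criterion checks and
# detection of treatment-confounder feedback.

#' Create a directed acyclic graph
#'
#' Builds a small labelled DAG from an edge list, with optional unmeasured
#' (latent) nodes and analysis roles (exposure / confounder / outcome /
#' baseline) carrying a time index. Acyclicity is verified at construction.
#'
#' @param edges Either a two-column data.frame (`from`, `to`) or a character
#'   vector of `"A -> B"` strings.
#' @param latent Character vector of unmeasured node names.
#' @param roles Optional data.frame with columns `node`, `role`
#'   (one of `"exposure"`, `"confounder"`, `"outcome"`, `"baseline"`,
#'   `"unmeasured"`) and `time` (integer or `NA`).
#' @param nodes Optional character vector of node names (isolated nodes may be
#'   listed here; nodes appearing in `edges` are added automatically).
#' @return An object of class `occmsm_dag`.
#' @export
#' @examples
#' g <- dag_create(c("L -> A", "L -> Y", "A -> Y"))
#' d_separated(g, "A", "Y", "L")
dag_create <- function(edges, latent = character(), roles = NULL,
                       nodes = character()) {
  edges <- parse_edges(edges)
  nodes <- unique(c(nodes, edges$from, edges$to, latent,
                    if (!is.null(roles)) roles$node))
  if (length(nodes) == 0L) validation_error("DAG has no nodes")
  if (anyDuplicated(paste(edges$from, edges$to)))
    validation_error("duplicate edges in DAG definition")
  if (any(edges$from == edges$to)) validation_error("self-loop in DAG definition")
  bad <- setdiff(latent, nodes)
  if (length(bad)) validation_error(paste("unknown latent node:", bad[1]))
  g <- structure(list(
    nodes = nodes,
    edges = edges,
    parents = split_edges(edges$to, edges$from, nodes),
    children = split_edges(edges$from, edges$to, nodes),
    latent = nodes %in% latent,
    roles = validate_roles(roles, nodes)
  ), class = "occmsm_dag")
  names(g$latent) <- nodes
  if (is.null(topological_order(g)))
    validation_error("graph is cyclic: no topological order exists")
  g
}

parse_edges <- function(edges) {
  if (is.character(edges)) {
    edges <- edges[nzchar(trimws(edges))]
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      validation_error("edges must be written as 'src -> dst'")
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1L)),
                        to   = trimws(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges)))
    validation_error("edges must be 'src -> dst' strings or a from/to data.frame")
  data.frame(from = as.character(edges$from), to = as.character(edges$to),
             stringsAsFactors = FALSE)
}

split_edges <- function(key, val, nodes) {
  out <- split(val, factor(key, levels = nodes))
  lapply(out, as.character)
}

validate_roles <- function(roles, nodes) {
  if (is.null(roles)) return(NULL)
  roles <- as.data.frame(roles)
  if (!all(c("node", "role") %in% names(roles)))
    validation_error("roles need columns node, role")
  if (is.null(roles$time)) roles$time <- NA_integer_
  ok <- c("exposure", "confounder", "outcome", "baseline", "unmeasured")
  if (!all(roles$role %in% ok))
    validation_error(paste("unknown role:", setdiff(roles$role, ok)[1]))
  bad <- setdiff(roles$node, nodes)
  if (length(bad)) validation_error(paste("role refers to unknown node:", bad[1]))
  roles$time <- as.integer(roles$time)
  roles
}

# Kahn's algorithm; NULL if cyclic.
topological_order <- function(dag) {
  indeg <- vapply(dag$parents, length, 1L)
  order <- character(0)
  queue <- names(indeg)[indeg == 0L]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (c_ in dag$children[[v]]) {
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) queue <- c(queue, c_)
    }
  }
  if (length(order) == length(dag$nodes)) order else NULL
}

check_nodes <- function(dag, x) {
  bad <- setdiff(x, dag$nodes)
  if (length(bad)) validation_error(paste("unknown node:", bad[1]))
  invisible(x)
}

# All ancestors (resp. descendants) of `set`, optionally including the set.
node_closure <- function(dag, set, direction = c("parents", "children"),
                         inclusive = TRUE) {
  direction <- match.arg(direction)
  adj <- dag[[direction]]
  seen <- character(0)
  frontier <- set
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (inclusive) unique(c(set, seen)) else setdiff(seen, set)
}

#' Ancestors and descendants of a node set
#'
#' @param dag An `occmsm_dag`.
#' @param x Character vector of node names.
#' @param inclusive Include `x` itself in the result?
#' @return Character vector of node names.
#' @export
dag_ancestors <- function(dag, x, inclusive = TRUE) {
  check_nodes(dag, x)
  node_closure(dag, x, "parents", inclusive)
}

#' @rdname dag_ancestors
#' @export
dag_descendants <- function(dag, x, inclusive = TRUE) {
  check_nodes(dag, x)
  node_closure(dag, x, "children", inclusive)
}

#' Test d-separation of two node sets given a conditioning set
#'
#' Decides whether every path between `x` and `y` is blocked given `z` under
#' the usual rules: a non-collider blocks when it is conditioned on; a
#' collider blocks unless it, or one of its descendants, is conditioned on.
#' Implemented as a reachability search over (node, travel direction) states
#' (Bayes-ball style), linear in the number of edges.
#'
#' @param dag An `occmsm_dag`.
#' @param x,y,z Character vectors of node names; `x`, `y`, `z` must be
#'   disjoint (`z` may be empty).
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @export
#' @examples
#' chain <- dag_create(c("A -> B", "B -> C"))
#' d_separated(chain, "A", "C", "B")   # TRUE
#' d_separated(chain, "A", "C")        # FALSE
d_separated <- function(dag, x, y, z = character()) {
  check_nodes(dag, c(x, y, z))
  if (length(intersect(x, y)) || length(intersect(x, z)) ||
      length(intersect(y, z)))
    validation_error("x, y and z must be disjoint node sets")
  an_z <- node_closure(dag, z, "parents", inclusive = TRUE)
  # states: (node, direction of arrival); "up" = moving against arrows is
  # allowed as if arriving from a child, "down" = arriving from a parent.
  seen_up <- seen_down <- setNames(logical(length(dag$nodes)), dag$nodes)
  queue_node <- x
  queue_dir <- rep("up", length(x))
  while (length(queue_node)) {
    v <- queue_node[1]; dir <- queue_dir[1]
    queue_node <- queue_node[-1]; queue_dir <- queue_dir[-1]
    if (dir == "up") {
      if (seen_up[v]) next
      seen_up[v] <- TRUE
    } else {
      if (seen_down[v]) next
      seen_down[v] <- TRUE
    }
    in_z <- v %in% z
    if (!in_z && v %in% y) return(FALSE)
    if (dir == "up" && !in_z) {
      for (p in dag$parents[[v]]) { queue_node <- c(queue_node, p); queue_dir <- c(queue_dir, "up") }
      for (ch in dag$children[[v]]) { queue_node <- c(queue_node, ch); queue_dir <- c(queue_dir, "down") }
    } else if (dir == "down") {
      if (!in_z)
        for (ch in dag$children[[v]]) { queue_node <- c(queue_node, ch); queue_dir <- c(queue_dir, "down") }
      if (v %in% an_z)
        for (p in dag$parents[[v]]) { queue_node <- c(queue_node, p); queue_dir <- c(queue_dir, "up") }
    }
  }
  TRUE
}

#' Check the backdoor criterion for an adjustment set
#'
#' `z` satisfies the backdoor criterion relative to exposure set `x` and
#' outcome `y` when (i) no node of `z` is a descendant of any node of `x`, and
#' (ii) `z` d-separates `x` from `y` in the graph with all edges out of `x`
#' removed. `z` may contain only measured nodes.
#'
#' @inheritParams d_separated
#' @param y A single outcome node.
#' @return `TRUE` if `z` is a valid backdoor adjustment set.
#' @export
#' @examples
#' tri <- dag_create(c("L -> A", "L -> Y", "A -> Y"))
#' backdoor_valid(tri, "A", "Y", "L")          # TRUE
#' backdoor_valid(tri, "A", "Y", character())  # FALSE
backdoor_valid <- function(dag, x, y, z = character()) {
  check_nodes(dag, c(x, y, z))
  if (length(y) != 1L) validation_error("y must be a single outcome node")
  if (any(dag$latent[z]))
    validation_error("adjustment set may contain only measured nodes")
  if (length(intersect(z, node_closure(dag, x, "children", inclusive = TRUE))))
    return(FALSE)
  keep <- !(dag$edges$from %in% x)
  g2 <- dag_create(dag$edges[keep, , drop = FALSE],
                   latent = dag$nodes[dag$latent],
                   roles = dag$roles, nodes = dag$nodes)
  d_separated(g2, x, y, z)
}

# Shortest directed path from -> to as a node sequence, or NULL.
directed_path <- function(dag, from, to) {
  if (from == to) return(from)
  prev <- setNames(rep(NA_character_, length(dag$nodes)), dag$nodes)
  queue <- from
  prev[from] <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (ch in dag$children[[v]]) {
      if (is.na(prev[ch])) {
        prev[ch] <- v
        if (ch == to) {
          path <- to
          while (path[1] != from) path <- c(prev[[path[1]]], path)
          return(unname(path))
        }
        queue <- c(queue, ch)
      }
    }
  }
  NULL
}

#' Detect treatment-confounder feedback
#'
#' A DAG exhibits treatment-confounder feedback when some time-varying
#' confounder is (i) a descendant of an earlier exposure, (ii) has a directed
#' path into a later (or same-time) exposure, and (iii) is associated with the
#' outcome either through a directed path or through a shared unmeasured
#' cause. Under this structure no measured adjustment set identifies the
#' exposure effect by plain regression, motivating inverse-probability
#' weighting.
#'
#' @param dag An `occmsm_dag` with roles assigned (exposures and outcome must
#'   carry time indices; see [occupancy_dag()]).
#' @return A list with elements `tcf` (logical) and `witnesses`, a list of
#'   witness path sets (each with the confounder name and the three node
#'   sequences establishing conditions i-iii).
#' @export
detect_tcf <- function(dag) {
  r <- dag$roles
  if (is.null(r) || !any(r$role == "exposure") || !any(r$role == "outcome"))
    config_error("detect_tcf needs roles with at least exposures and an outcome")
  exps <- r[r$role == "exposure", ]
  if (any(is.na(exps$time)))
    config_error("exposure roles must carry a time index")
  outc <- r[r$role == "outcome", ]
  y <- outc$node[which.max(ifelse(is.na(outc$time), -Inf, outc$time))]
  latent_nodes <- dag$nodes[dag$latent]
  # outcome associations must run outside the exposure pathway: look for them
  # in the graph with every exposure's outgoing edges removed
  keep <- !(dag$edges$from %in% exps$node)
  g_noexp <- dag_create(dag$edges[keep, , drop = FALSE],
                        latent = latent_nodes, roles = dag$roles,
                        nodes = dag$nodes)
  witnesses <- list()
  for (i in seq_len(sum(r$role == "confounder"))) {
    l <- r[r$role == "confounder", ][i, ]
    earlier <- exps$node[!is.na(l$time) & exps$time < l$time]
    later <- exps$node[is.na(l$time) | exps$time >= l$time]
    from_exp <- NULL
    for (a in earlier) {
      p <- directed_path(dag, a, l$node)
      if (!is.null(p) && length(p) > 1L) { from_exp <- p; break }
    }
    if (is.null(from_exp)) next
    to_exp <- NULL
    for (a in later) {
      p <- directed_path(dag, l$node, a)
      if (!is.null(p) && length(p) > 1L) { to_exp <- p; break }
    }
    if (is.null(to_exp)) next
    outcome_link <- directed_path(g_noexp, l$node, y)
    if (is.null(outcome_link)) {
      for (u in latent_nodes) {
        pu_l <- directed_path(g_noexp, u, l$node)
        pu_y <- directed_path(g_noexp, u, y)
        if (!is.null(pu_l) && !is.null(pu_y) && length(pu_y) > 1L) {
          outcome_link <- c(rev(pu_l), pu_y[-1])
          break
        }
      }
    }
    if (is.null(outcome_link)) next
    witnesses[[length(witnesses) + 1L]] <-
      list(confounder = l$node, from_exposure = from_exp,
           to_exposure = to_exp, outcome_link = outcome_link)
  }
  list(tcf = length(witnesses) > 0L, witnesses = witnesses)
}

#' The built-in two-day occupancy DAG
#'
#' Encodes the working causal diagram for two consecutive hospital days:
#' capacity-utilization exposures `CU1`, `CU2`; time-varying confounders
#' patient turnover `PT1`, `PT2` and mean clinical complexity `PCCL1`,
#' `PCCL2`; mortality `M1`, `M2`; baseline covariates `C`; and an unmeasured
#' staffing-like variable `U` driving turnover and late mortality. Day-one
#' exposure feeds the day-two confounder (`CU1 -> PT2`), which, combined with
#' `PT2 <- U -> M2`, produces treatment-confounder feedback.
#'
#' @return An `occmsm_dag`.
#' @export
#' @examples
#' g <- occupancy_dag()
#' detect_tcf(g)$tcf
occupancy_dag <- function() {
  edges <- c(
    "C -> CU1", "C -> CU2", "C -> M1", "C -> M2",
    "PT1 -> CU1", "PCCL1 -> CU1",
    "CU1 -> M1", "CU1 -> CU2", "CU1 -> PT2",
    "PT2 -> CU2", "PCCL2 -> CU2",
    "CU2 -> M2",
    "U -> PT1", "U -> PT2", "U -> M2",
    "PCCL1 -> PCCL2"
  )
  roles <- data.frame(
    node = c("CU1", "CU2", "PT1", "PCCL1", "PT2", "PCCL2", "M1", "M2", "C", "U"),
    role = c("exposure", "exposure", "confounder", "confounder", "confounder",
             "confounder", "outcome", "outcome", "baseline", "unmeasured"),
    time = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L, NA_integer_, NA_integer_)
  )
  dag_create(edges, latent = "U", roles = roles)
}

#' Read and write the plain-text DAG format
#'
#' One edge per line as `src -> dst`; `latent NAME` marks unmeasured nodes;
#' `role NODE ROLE [TIME]` assigns analysis roles; `node NAME` declares an
#' isolated node; `#` starts a comment. [dag_write()] emits the same format so
#' the two functions round-trip.
#'
#' @param path File path.
#' @param dag An `occmsm_dag`.
#' @return [dag_read()] returns an `occmsm_dag`; [dag_write()] returns `path`
#'   invisibly.
#' @export
dag_read <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_latent <- startsWith(lines, "latent ")
  is_role <- startsWith(lines, "role ")
  is_node <- startsWith(lines, "node ")
  latent <- trimws(sub("^latent ", "", lines[is_latent]))
  nodes <- trimws(sub("^node ", "", lines[is_node]))
  roles <- NULL
  if (any(is_role)) {
    parts <- strsplit(trimws(sub("^role ", "", lines[is_role])), "\\s+")
    if (any(lengths(parts) < 2L))
      validation_error("role lines must read 'role NODE ROLE [TIME]'")
    roles <- data.frame(
      node = vapply(parts, `[`, "", 1L),
      role = vapply(parts, `[`, "", 2L),
      time = vapply(parts, function(p)
        if (length(p) >= 3L) as.integer(p[3]) else NA_integer_, 1L)
    )
  }
  edges <- lines[!(is_latent | is_role | is_node)]
  dag_create(edges, latent = latent, roles = roles, nodes = nodes)
}

#' @rdname dag_read
#' @export
dag_write <- function(dag, path) {
  isolated <- setdiff(dag$nodes, c(dag$edges$from, dag$edges$to,
                                   dag$nodes[dag$latent], dag$roles$node))
  lines <- c(
    paste(dag$edges$from, "->", dag$edges$to),
    if (any(dag$latent)) paste("latent", dag$nodes[dag$latent]),
    if (!is.null(dag$roles))
      trimws(paste("role", dag$roles$node, dag$roles$role,
                   ifelse(is.na(dag$roles$time), "", dag$roles$time))),
    if (length(isolated)) paste("node", isolated)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.occmsm_dag <- function(x, ...) {
  cat(sprintf("<occmsm_dag> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (any(x$latent))
    cat("  unmeasured:", paste(x$nodes[x$latent], collapse = ", "), "\n")
  invisible(x)
}
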