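# Independent oracles and fixture builders shared across the suite.
# The d-separation oracle enumerates every simple path and applies the
# blocking rules directly; it shares no code with the package's
# reachability-based implementation.

# ---- path-enumeration d-separation oracle -----------------------------------

oracle_all_paths <- function(edges, x, y, nodes) {
  # undirected simple paths from x to y, returned as node sequences
  adj <- lapply(setNames(nodes, nodes), function(v)
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
  }
  walk(x)
  paths
}

oracle_descendants <- function(edges, v) {
  out <- v
  repeat {
    nxt <- unique(edges$to[edges$from %in% out])
    if (all(nxt %in% out)) return(out)
    out <- unique(c(out, nxt))
  }
}

oracle_path_blocked <- function(edges, path, z) {
  if (length(path) <= 2L) return(FALSE)
  has_edge <- function(a, b) any(edges$from == a & edges$to == b)
  for (k in 2:(length(path) - 1L)) {
    v <- path[k]
    into_left <- has_edge(path[k - 1L], v)
    into_right <- has_edge(path[k + 1L], v)
    collider <- into_left && into_right
    if (collider) {
      if (!any(oracle_descendants(edges, v) %in% z)) return(TRUE)
    } else {
      if (v %in% z) return(TRUE)
    }
  }
  FALSE
}

oracle_d_separated <- function(dag, x, y, z = character()) {
  edges <- dag$edges
  for (xi in x) for (yi in y) {
    paths <- oracle_all_paths(edges, xi, yi, dag$nodes)
    for (p in paths)
      if (!oracle_path_blocked(edges, p, z)) return(FALSE)
  }
  TRUE
}

# ---- DAG generators ---------------------------------------------------------

# All DAGs on `nodes`: every orientation assignment (absent / forward /
# backward) over the node pairs, filtered to acyclic ones.
enumerate_dags <- function(nodes) {
  pairs <- utils::combn(nodes, 2L)
  n_pairs <- ncol(pairs)
  out <- list()
  for (code in 0:(3^n_pairs - 1L)) {
    digits <- (code %/% 3^(seq_len(n_pairs) - 1L)) %% 3
    from <- character(0); to <- character(0)
    for (j in seq_len(n_pairs)) {
      if (digits[j] == 1) { from <- c(from, pairs[1, j]); to <- c(to, pairs[2, j]) }
      if (digits[j] == 2) { from <- c(from, pairs[2, j]); to <- c(to, pairs[1, j]) }
    }
    g <- tryCatch(
      dag_create(data.frame(from = from, to = to), nodes = nodes),
      occmsm_validation_error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

random_dag <- function(n_nodes, p_edge = 0.4) {
  nodes <- paste0("N", seq_len(n_nodes))
  ord <- sample(nodes)
  from <- character(0); to <- character(0)
  for (i in seq_len(n_nodes - 1L))
    for (j in (i + 1L):n_nodes)
      if (runif(1) < p_edge) { from <- c(from, ord[i]); to <- c(to, ord[j]) }
  dag_create(data.frame(from = from, to = to), nodes = nodes)
}

# all (x, y, z) queries with singleton x, y over a small node set
dsep_queries <- function(nodes, max_z = length(nodes) - 2L) {
  qs <- list()
  for (x in nodes) for (y in setdiff(nodes, x)) {
    rest <- setdiff(nodes, c(x, y))
    for (k in 0:min(max_z, length(rest))) {
      zsets <- if (k == 0L) list(character(0)) else
        asplit(utils::combn(rest, k), 2L)
      for (z in zsets) qs[[length(qs) + 1L]] <- list(x = x, y = y, z = as.character(z))
    }
  }
  qs
}

# ---- episode-record fixtures ------------------------------------------------

# hand-written record builder with sensible defaults
make_records <- function(admission_day, discharge_day, hospital_id = 1L,
                         hospital_type = 1L, died = FALSE, death_day = NA,
                         sex = "female", age_group = 10L, pccl = 0L,
                         elixhauser_weight = 0, weekend_admission = FALSE) {
  n <- length(admission_day)
  data.frame(
    patient_id = seq_len(n),
    hospital_id = rep_len(hospital_id, n),
    hospital_type = rep_len(hospital_type, n),
    admission_day = as.integer(admission_day),
    discharge_day = as.integer(discharge_day),
    died = rep_len(died, n),
    death_day = as.integer(rep_len(death_day, n)),
    sex = rep_len(sex, n),
    age_group = rep_len(age_group, n),
    pccl = rep_len(pccl, n),
    elixhauser_weight = rep_len(elixhauser_weight, n),
    weekend_admission = rep_len(weekend_admission, n)
  )
}

# small simulation configs reused across tests
tiny_sim <- function(seed = 1L, ...) {
  sim_config(n_hospitals = 2L, hospital_sizes = c(40, 30),
             hospital_types = c(2L, 5L), year_length = 120L,
             seed = seed, ...)
}

small_sim <- function(seed = 1L, ...) {
  sim_config(n_hospitals = 3L, hospital_sizes = c(60, 45, 30),
             hospital_types = c(2L, 3L, 5L), year_length = 150L,
             seed = seed, ...)
}

# run the analysis pipeline up to person-days on a generated cohort
cohort_persondays <- function(config) {
  co <- generate_cohort(config)
  rec <- apply_inclusion_filters(co$records, config$year_length, quiet = TRUE)
  hd <- build_daily_series(rec, config$year_length, config$weekday_of_day1)
  thr <- derive_threshold(hd, config$exposure_percentile)
  list(cohort = co, records = rec, hospital_days = hd, thresholds = thr,
       persondays = expand_person_days(rec, hd, thr))
}
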