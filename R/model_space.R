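# Rate positions are always ordered (ac, ag, at, cg, ct, gt).
RATE_NAMES <- c("ac", "ag", "at", "cg", "ct", "gt")
TRANSITIONS <- c(2L, 5L)  # ag, ct
NAMED_MODELS <- c("111111", "121121", "121131", "123321", "123341",
                  "123425", "123456", "123345", "123324")

#' Canonicalize a substitution-model code
#'
#' A time-reversible nucleotide substitution model is identified by a
#' six-symbol code over the rate positions (ac, ag, at, cg, ct, gt):
#' positions carrying the same symbol share one exchangeability rate.
#' The canonical (restricted-growth) form relabels groups so the first
#' position is 1 and each new group label is one more than the largest
#' label seen so far, e.g. "646646" and "212212" both canonicalize to
#' "121121" (HKY).
#'
#' @param code A 6-character string of digits, or an integer vector of
#'   length 6.  Equal entries define the rate grouping.
#' @return A 6-character canonical model string.
#' @examples
#' canonicalize_model("646646")  # "121121"
#' canonicalize_model(c(2, 1, 2, 2, 1, 2))
#' @export
canonicalize_model <- function(code) {
  code <- parse_model_code(code)
  relabel <- integer(max(code))
  nxt <- 1L
  out <- integer(6L)
  for (i in 1:6) {
    g <- code[i]
    if (relabel[g] == 0L) {
      relabel[g] <- nxt
      nxt <- nxt + 1L
    }
    out[i] <- relabel[g]
  }
  paste(out, collapse = "")
}

parse_model_code <- function(code) {
  if (is.character(code)) {
    stopifnot(length(code) == 1L)
    code <- as.integer(strsplit(code, "", fixed = TRUE)[[1]])
  }
  code <- as.integer(code)
  if (length(code) != 6L || anyNA(code) || any(code < 1L))
    stop("a model code must have six positive integer entries")
  code
}

# memo cache for per-model static quantities (at most 203 distinct keys)
.model_memo <- new.env(parent = emptyenv())

model_memo <- function(key, fn) {
  hit <- .model_memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- fn()
  assign(key, val, envir = .model_memo)
  val
}

#' Rate groups of a model
#'
#' @param model Canonical model string.
#' @return A list of integer vectors, one per group, giving the rate
#'   positions (1 = ac, ..., 6 = gt) in that group, ordered by group label.
#' @export
model_groups <- function(model) {
  if (is.character(model) && length(model) == 1L)
    return(model_memo(paste0("g", model), function()
      unname(split(seq_len(6L), parse_model_code(model)))))
  code <- parse_model_code(model)
  unname(split(seq_len(6L), code))
}

#' Degrees of freedom of a model
#'
#' Number of free rate parameters: one fewer than the number of rate
#' groups, because the six expanded rates are constrained to sum to 6.
#'
#' @param model Canonical model string.
#' @return Integer in 0..5.
#' @export
model_dof <- function(model) {
  length(model_groups(model)) - 1L
}

# All set partitions of n labelled elements as restricted-growth strings.
rg_strings <- function(n) {
  grow <- function(prefix, mx) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (g in seq_len(mx + 1L))
      out <- c(out, grow(c(prefix, g), max(mx, g)))
    out
  }
  vapply(grow(1L, 1L), paste, "", collapse = "")
}

#' Enumerate a substitution-model set
#'
#' Three model sets are supported: `"all"` (every grouping of the six
#' rates; 203 models), `"tstv"` (groupings that never place a transition
#' rate (ag, ct) and a transversion rate in the same group, plus the
#' all-equal model 111111; 31 models) and `"named"` (Jukes-Cantor, HKY,
#' TN93, K81, TIM, TVM, GTR and the two intermediates 123345 and 123324;
#' 9 models).
#'
#' @param set_kind One of `"all"`, `"tstv"`, `"named"`.
#' @return Sorted character vector of canonical model strings.
#' @examples
#' length(enumerate_models("all"))   # 203
#' length(enumerate_models("tstv"))  # 31
#' @export
enumerate_models <- function(set_kind = c("all", "tstv", "named")) {
  set_kind <- match.arg(set_kind)
  all <- sort(rg_strings(6L))
  switch(set_kind,
    all = all,
    tstv = {
      ok <- vapply(all, function(m) {
        gs <- model_groups(m)
        !any(vapply(gs, function(g)
          any(g %in% TRANSITIONS) && any(!(g %in% TRANSITIONS)), TRUE))
      }, TRUE)
      sort(unique(c(all[ok], "111111")))
    },
    named = sort(NAMED_MODELS))
}

# TRUE iff `child` refines `parent` by splitting exactly one group in two.
refines_by_one_split <- function(parent, child) {
  gp <- model_groups(parent)
  gc <- model_groups(child)
  if (length(gc) != length(gp) + 1L) return(FALSE)
  all(vapply(gc, function(g)
    any(vapply(gp, function(h) all(g %in% h), TRUE)), TRUE))
}

#' Build the split/merge model graph
#'
#' Nodes are the models of a set; a directed split edge runs from a model
#' to every member of the set obtained by splitting exactly one of its
#' rate groups into two non-empty parts.  Merge edges are the reverses.
#'
#' @param models Character vector of canonical model strings
#'   (e.g. from [enumerate_models()]).
#' @return An object of class `model_graph`: a list with elements
#'   `models`, `children` (named list of split targets) and `parents`
#'   (named list of merge targets).
#' @export
model_graph <- function(models) {
  models <- sort(unique(models))
  stopifnot(all(vapply(models, function(m) canonicalize_model(m) == m, TRUE)))
  children <- lapply(models, function(a)
    models[vapply(models, function(b) refines_by_one_split(a, b), TRUE)])
  parents <- lapply(models, function(b)
    models[vapply(models, function(a) refines_by_one_split(a, b), TRUE)])
  children <- stats::setNames(children, models)
  parents <- stats::setNames(parents, models)
  # precomputed per-edge bookkeeping for the sampler's hot loop
  info <- new.env(parent = emptyenv())
  for (m in models) {
    gs <- model_groups(m)
    sizes <- lengths(gs)
    splits <- lapply(children[[m]], function(child) {
      map <- vapply(model_groups(child), function(g)
        which(vapply(gs, function(h) all(g %in% h), TRUE))[1], 1L)
      s <- map[duplicated(map) | duplicated(map, fromLast = TRUE)][1]
      ij <- which(map == s)
      csz <- lengths(model_groups(child))
      list(child = child, s = s, i1 = ij[1], i2 = ij[2],
           ni = csz[ij[1]], nj = csz[ij[2]], map = map)
    })
    merges <- lapply(parents[[m]], function(parent) {
      map <- vapply(gs, function(g)
        which(vapply(model_groups(parent), function(h) all(g %in% h),
                     TRUE))[1], 1L)
      s <- map[duplicated(map) | duplicated(map, fromLast = TRUE)][1]
      ij <- which(map == s)
      list(parent = parent, s = s, i1 = ij[1], i2 = ij[2],
           ni = sizes[ij[1]], nj = sizes[ij[2]], map = map,
           nparent = length(gs) - 1L)
    })
    assign(m, list(sizes = sizes, code = parse_model_code(m),
                   ngroups = length(sizes),
                   splits = splits, merges = merges), envir = info)
  }
  structure(list(models = models, children = children, parents = parents,
                 info = info),
            class = "model_graph")
}

#' @export
print.model_graph <- function(x, ...) {
  cat("model_graph:", length(x$models), "models,",
      sum(lengths(x$children)), "split edges\n")
  invisible(x)
}

#' Split / merge candidates of a model
#'
#' @param model Canonical model string, a node of `graph`.
#' @param graph A [model_graph()].
#' @return Character vector of candidate models (possibly empty: GTR has
#'   no split candidates, 111111 no merge candidates).
#' @export
split_candidates <- function(model, graph) {
  if (!model %in% graph$models) stop("model ", model, " is not in the graph")
  graph$children[[model]]
}

#' @rdname split_candidates
#' @export
merge_candidates <- function(model, graph) {
  if (!model %in% graph$models) stop("model ", model, " is not in the graph")
  graph$parents[[model]]
}

#' Log prior probability of a substitution model
#'
#' Either uniform over the models of the set, or uniform over the number
#' of free rate parameters (degrees of freedom 0..5, each class receiving
#' total mass 1/6 shared equally within the class, so Jukes-Cantor and
#' GTR each get exactly 1/6).
#'
#' @param model Canonical model string.
#' @param models Character vector: the model set.
#' @param prior_kind `"uniform"` (over models) or `"dof"` (uniform over
#'   parameter count).
#' @return Log prior probability.
#' @export
model_log_prior <- function(model, models, prior_kind = c("uniform", "dof")) {
  prior_kind <- match.arg(prior_kind)
  if (!model %in% models) stop("model ", model, " is not in the model set")
  if (prior_kind == "uniform") return(-log(length(models)))
  dofs <- vapply(models, model_dof, 1L)
  -log(6) - log(sum(dofs == model_dof(model)))
}

#' Export a model graph as DOT
#'
#' @param graph A [model_graph()].
#' @param path Optional file to write to.
#' @return The DOT text, invisibly if written to a file.
#' @export
model_graph_dot <- function(graph, path = NULL) {
  edges <- unlist(lapply(graph$models, function(m)
    sprintf("  \"%s\" -> \"%s\";", m, graph$children[[m]])))
  txt <- paste(c("digraph model_space {", edges, "}"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
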