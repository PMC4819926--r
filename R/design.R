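# Declarative experimental designs and the nested model hierarchy.
#
# A design is the factorial condition structure of one experiment plus the
# rules mapping a condition cell to race parameters: which accumulator matches
# the stimulus, and (for the choice-bias design) how a directional cue relates
# to each accumulator (biased toward / against / neutral). A model spec says,
# for each LBA parameter type, over which factors that parameter may vary.

PARAM_TYPES <- c("v", "sv", "A", "b_minus_A", "t0")
FACTOR_ORDER <- c("session", "cue", "direction", "sat", "coherence", "iti",
                  "resptype", "cueacc")

#' Build an experimental design
#'
#' Three built-in random-dot-motion designs are provided:
#' \describe{
#'   \item{`"bias"`}{probabilistic cueing: cues are reliable (valid on 90\% of
#'     trials), moderate (70\%) or neutral, crossed with motion direction and
#'     session; 2 x 5 x 2 = 20 cells.}
#'   \item{`"sat"`}{speed/neutral/accuracy cueing crossed with session;
#'     2 x 3 = 6 cells.}
#'   \item{`"difficulty"`}{motion coherence 5/10/20/40/80\% crossed with
#'     inter-trial interval (short = 500 ms, long = 4300 ms) and session;
#'     2 x 5 x 2 = 20 cells.}
#' }
#' A custom design is built from `config = list(name =, factors = list(...))`
#' where each factor is a character vector of ordered levels (first level is
#' the reference).
#'
#' @param experiment one of `"bias"`, `"sat"`, `"difficulty"`, or `"custom"`.
#' @param config for `"custom"`, the design configuration list.
#' @return an object of class `lba_design` with the factorial cell table, the
#'   per-accumulator parameter-level table, and the response alternatives.
#' @export
build_design <- function(experiment = c("bias", "sat", "difficulty", "custom"),
                         config = NULL) {
  experiment <- match.arg(experiment)
  factors <- switch(experiment,
    bias = list(session = c("behavioral", "mri"),
                cue = c("L9", "L7", "N", "R7", "R9"),
                direction = c("left", "right")),
    sat = list(session = c("behavioral", "mri"),
               sat = c("speed", "neutral", "accuracy")),
    difficulty = list(session = c("behavioral", "mri"),
                      coherence = c("5", "10", "20", "40", "80"),
                      iti = c("short", "long")),
    custom = {
      if (!is.list(config) || is.null(config$factors))
        stop("custom design needs config$factors", call. = FALSE)
      config$factors
    })
  for (nm in names(factors)) {
    lv <- factors[[nm]]
    if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv))
      stop("malformed factor `", nm,
           "`: need >= 2 distinct character levels", call. = FALSE)
  }
  name <- if (experiment == "custom") config$name %||% "custom" else experiment
  # canonical cell table: later factors vary slowest
  cells <- expand.grid(factors, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[rev(seq_along(factors))]
  cells <- cells[do.call(order, lapply(names(factors), function(nm)
    match(cells[[nm]], factors[[nm]]))), , drop = FALSE]
  cells <- cells[names(factors)]
  rownames(cells) <- NULL
  cells$cell_id <- seq_len(nrow(cells))

  # per-accumulator parameter-level table: 2 rows per cell (correct, error)
  ptab <- cells[rep(seq_len(nrow(cells)), each = 2L), , drop = FALSE]
  ptab$acc <- rep(1:2, nrow(cells))
  ptab$resptype <- ifelse(ptab$acc == 1L, "correct", "error")
  pseudo <- list(resptype = c("correct", "error"))
  if (experiment == "bias") {
    side <- ifelse(ptab$resptype == "correct", ptab$direction,
                   ifelse(ptab$direction == "left", "right", "left"))
    ptab$cueacc <- cue_congruence(ptab$cue, side)
    pseudo$cueacc <- c("neutral", "toward", "against")
  }
  rownames(ptab) <- NULL

  structure(list(name = name, factors = factors, pseudo_factors = pseudo,
                 cells = cells, paramtab = ptab,
                 responses = c("left", "right")),
            class = "lba_design")
}

# A leftward cue biases the left accumulator regardless of stimulus direction.
cue_congruence <- function(cue, side) {
  ifelse(cue == "N", "neutral",
         ifelse(substr(cue, 1, 1) == "L",
                ifelse(side == "left", "toward", "against"),
                ifelse(side == "right", "toward", "against")))
}

#' @export
print.lba_design <- function(x, ...) {
  cat(sprintf("<lba_design> %s: %d cells; factors %s\n", x$name,
              nrow(x$cells),
              paste(sprintf("%s(%d)", names(x$factors),
                            lengths(x$factors)), collapse = " x ")))
  invisible(x)
}

design_factor_levels <- function(design, factor) {
  design$factors[[factor]] %||% design$pseudo_factors[[factor]] %||%
    stop("unknown factor `", factor, "` in design ", design$name, call. = FALSE)
}

#' Construct a model specification
#'
#' A model spec lists, for each LBA parameter type, the factors over which it
#' varies (the empty set means one value for all conditions). Response type
#' (`"resptype"`, i.e. stimulus-matching vs mismatching accumulator) and cue
#' congruence (`"cueacc"`) are pseudo-factors available alongside the design
#' factors. Non-decision time is shared by the racing accumulators and cannot
#' vary over per-accumulator pseudo-factors.
#'
#' @param design an [build_design()] object.
#' @param v,sv,A,b_minus_A,t0 character vectors of factor names (possibly
#'   empty) for each parameter type.
#' @return an object of class `lba_model_spec` with a canonical `id` and
#'   free-parameter count `k`.
#' @export
model_spec <- function(design, v = character(), sv = character(),
                       A = character(), b_minus_A = character(),
                       t0 = character()) {
  fac <- list(v = v, sv = sv, A = A, b_minus_A = b_minus_A, t0 = t0)
  avail <- c(names(design$factors), names(design$pseudo_factors))
  for (type in PARAM_TYPES) {
    f <- fac[[type]]
    bad <- setdiff(f, avail)
    if (length(bad)) stop("unknown factor(s) for ", type, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (type == "t0" && any(f %in% c("resptype", "cueacc")))
      stop("t0 is shared across accumulators and cannot vary by ",
           "resptype/cueacc", call. = FALSE)
    fac[[type]] <- intersect(FACTOR_ORDER, f)  # canonical order
  }
  spec <- structure(list(design = design, factors = fac), class = "lba_model_spec")
  spec$id <- spec_id(spec)
  spec$k <- spec_k(spec)
  spec
}

spec_id <- function(spec) {
  abbr <- c(session = "S", cue = "C", direction = "D", sat = "T",
            coherence = "H", iti = "I", resptype = "R", cueacc = "B")
  paste(vapply(PARAM_TYPES, function(type) {
    f <- spec$factors[[type]]
    paste0(sub("b_minus_A", "bA", type), ":",
           if (length(f)) paste(abbr[f], collapse = "+") else "1")
  }, character(1)), collapse = "|")
}

#' @export
print.lba_model_spec <- function(x, ...) {
  cat(sprintf("<lba_model_spec> %s (k = %d) on design %s\n",
              x$id, x$k, x$design$name))
  invisible(x)
}

# Parameter cells of one type: canonical table of factor-level combinations.
# The sv anchor (error accumulator / reference condition fixed at 1 for scale
# identifiability) is marked here.
spec_type_cells <- function(spec, type) {
  f <- spec$factors[[type]]
  design <- spec$design
  if (!length(f)) {
    cells <- data.frame(row.names = 1L)
    cells$cell_name <- type
  } else {
    lv <- lapply(f, design_factor_levels, design = design)
    names(lv) <- f
    cells <- expand.grid(lv, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    cells <- cells[rev(seq_along(f))]
    cells <- cells[do.call(order, lapply(f, function(nm)
      match(cells[[nm]], lv[[nm]]))), , drop = FALSE]
    cells <- cells[f]
    rownames(cells) <- NULL
    cells$cell_name <- paste(type, apply(cells[f], 1, paste, collapse = "."),
                             sep = ".")
  }
  if (type == "sv") {
    anchored <- rep(TRUE, nrow(cells))
    for (nm in f) {
      want <- if (nm == "resptype") "error" else design_factor_levels(design, nm)[1]
      anchored <- anchored & cells[[nm]] == want
    }
    cells$anchored <- anchored
  } else {
    cells$anchored <- FALSE
  }
  cells
}

spec_k <- function(spec) {
  sum(vapply(PARAM_TYPES, function(type) {
    cells <- spec_type_cells(spec, type)
    sum(!cells$anchored)
  }, numeric(1)))
}

# Index (into the type's cell table) of each row of the design's paramtab.
spec_type_index <- function(spec, type) {
  cells <- spec_type_cells(spec, type)
  f <- spec$factors[[type]]
  ptab <- spec$design$paramtab
  if (!length(f)) return(rep(1L, nrow(ptab)))
  key <- function(df) do.call(paste, c(df[f], sep = "\r"))
  match(key(ptab), key(cells))
}

#' Per-experiment top models
#'
#' The top model lets every parameter type vary across sessions, plus the
#' consensus condition effects of each paradigm: for the choice-bias design,
#' drift mean and SD vary by response type and the threshold gap `b - A`
#' varies by cue congruence per accumulator; for the speed-accuracy design,
#' `b - A`, drift mean and non-decision time additionally vary with the SAT
#' cue (drift SD varies by response type only); for the difficulty design,
#' drift mean and SD vary with coherence and response type, and `b - A`
#' additionally with the inter-trial interval.
#'
#' @param design an [build_design()] design (one of the three built-ins).
#' @return an `lba_model_spec`.
#' @export
top_model <- function(design) {
  stopifnot(inherits(design, "lba_design"))
  switch(design$name,
    bias = model_spec(design,
      v = c("session", "resptype"), sv = c("session", "resptype"),
      A = "session", b_minus_A = c("session", "cueacc"), t0 = "session"),
    sat = model_spec(design,
      v = c("session", "sat", "resptype"), sv = c("session", "resptype"),
      A = "session", b_minus_A = c("session", "sat"),
      t0 = c("session", "sat")),
    difficulty = model_spec(design,
      v = c("session", "coherence", "resptype"),
      sv = c("session", "coherence", "resptype"),
      A = "session", b_minus_A = c("session", "iti"), t0 = "session"),
    stop("no built-in top model for design `", design$name, "`", call. = FALSE))
}

#' Reduced top model for desk-scale session analyses
#'
#' Keeps response type as a locked factor on the drift parameters (so the
#' simplest models still distinguish correct from error evidence) and lets
#' each of the five parameter types optionally vary by session, giving a
#' 2^5 = 32-node hierarchy with [enumerate_hierarchy()].
#'
#' @param design an [build_design()] design.
#' @return an `lba_model_spec`.
#' @export
reduced_top_model <- function(design) {
  model_spec(design,
             v = c("session", "resptype"), sv = c("session", "resptype"),
             A = "session", b_minus_A = "session", t0 = "session")
}

powerset <- function(x) {
  if (!length(x)) return(list(character()))
  out <- list(character())
  for (el in x) out <- c(out, lapply(out, function(s) c(s, el)))
  out
}

#' Enumerate the nested model hierarchy under a top model
#'
#' Generates every model obtainable from the top model by fixing a parameter
#' type across one or more of its factors (dropping whole factors from its
#' dependence), i.e. the product lattice of subsets of each parameter type's
#' top factor set. Nodes are ordered by ascending free-parameter count; each
#' node records its immediate nested predecessors (one factor removed) for
#' warm-started fitting.
#'
#' @param top an `lba_model_spec` (the unique maximum of the lattice).
#' @param locked named list of factors that every node must retain for a given
#'   parameter type (e.g. `list(v = "resptype")`).
#' @param cap maximum node count before erroring (default 4096); restrict the
#'   top model if exceeded.
#' @return object of class `lba_hierarchy`: list of nodes, each with `spec`,
#'   `k`, `id` and `parents`/`children` (ids of immediate supersets/subsets).
#' @export
enumerate_hierarchy <- function(top, locked = list(), cap = 4096) {
  stopifnot(inherits(top, "lba_model_spec"))
  subsets <- lapply(PARAM_TYPES, function(type) {
    lock <- intersect(locked[[type]] %||% character(), top$factors[[type]])
    free <- setdiff(top$factors[[type]], lock)
    lapply(powerset(free), function(s) intersect(FACTOR_ORDER, c(lock, s)))
  })
  names(subsets) <- PARAM_TYPES
  n_nodes <- prod(lengths(subsets))
  if (n_nodes > cap)
    stop("hierarchy would contain ", n_nodes, " models (cap ", cap,
         "); restrict the top model or raise `cap`", call. = FALSE)
  grid <- expand.grid(lapply(subsets, seq_along), KEEP.OUT.ATTRS = FALSE)
  nodes <- lapply(seq_len(nrow(grid)), function(i) {
    fac <- lapply(PARAM_TYPES, function(type)
      subsets[[type]][[grid[i, type]]])
    names(fac) <- PARAM_TYPES
    spec <- model_spec(top$design, v = fac$v, sv = fac$sv, A = fac$A,
                       b_minus_A = fac$b_minus_A, t0 = fac$t0)
    list(spec = spec, id = spec$id, k = spec$k)
  })
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("internal: duplicate hierarchy nodes")
  ord <- order(vapply(nodes, `[[`, numeric(1), "k"), ids)
  nodes <- nodes[ord]
  ids <- ids[ord]
  by_id <- setNames(seq_along(nodes), ids)
  # immediate nesting links: remove exactly one factor from one type
  for (i in seq_along(nodes)) {
    spec <- nodes[[i]]$spec
    parents <- character()
    for (type in PARAM_TYPES) {
      extra <- setdiff(setdiff(top$factors[[type]], spec$factors[[type]]),
                       locked[[type]] %||% character())
      for (f in extra) {
        fac <- spec$factors
        fac[[type]] <- intersect(FACTOR_ORDER, c(fac[[type]], f))
        sup <- model_spec(top$design, v = fac$v, sv = fac$sv, A = fac$A,
                          b_minus_A = fac$b_minus_A, t0 = fac$t0)
        parents <- c(parents, sup$id)
      }
    }
    nodes[[i]]$parents <- parents
  }
  for (i in seq_along(nodes)) nodes[[i]]$children <- character()
  for (i in seq_along(nodes)) {
    for (p in nodes[[i]]$parents) {
      j <- by_id[[p]]
      nodes[[j]]$children <- c(nodes[[j]]$children, nodes[[i]]$id)
    }
  }
  structure(list(nodes = nodes, ids = ids, top_id = top$id,
                 design = top$design),
            class = "lba_hierarchy")
}

#' @export
print.lba_hierarchy <- function(x, ...) {
  ks <- vapply(x$nodes, `[[`, numeric(1), "k")
  cat(sprintf("<lba_hierarchy> %d models on design %s (k from %d to %d)\n",
              length(x$nodes), x$design$name, min(ks), max(ks)))
  invisible(x)
}
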