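# Parameter vectors for a model spec.
#
# The public currency is a *natural-scale* named vector with one entry per
# parameter cell (e.g. "v.mri.correct", "t0.behavioral"). For optimization it
# is mapped to an unconstrained *free* vector: log scale for sv, A, b - A and
# t0 (so positivity and b >= A hold by construction), identity for v. The sv
# cell of the error accumulator in the reference condition is anchored at 1
# (the LBA evidence scale is arbitrary) and never free.

LOG_SCALE_TYPES <- c("sv", "A", "b_minus_A", "t0")
POSITIVE_FLOOR <- 1e-8

#' Parameter-cell skeleton of a model spec
#'
#' Lists every parameter cell of a spec in canonical order, with its type,
#' name, whether it is log-transformed for optimization, and whether it is the
#' anchored sv cell (fixed at 1 for scale identifiability).
#'
#' @param spec an `lba_model_spec`.
#' @return data.frame with columns `type`, `cell_name`, `log_scale`,
#'   `anchored`.
#' @export
theta_skeleton <- function(spec) {
  out <- do.call(rbind, lapply(PARAM_TYPES, function(type) {
    cells <- spec_type_cells(spec, type)
    data.frame(type = type, cell_name = cells$cell_name,
               log_scale = type %in% LOG_SCALE_TYPES,
               anchored = cells$anchored, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Map a natural-scale parameter vector to the unconstrained free scale
#'
#' @param theta named natural-scale vector over all parameter cells of `spec`
#'   (anchored cells may be present; they are dropped).
#' @param spec an `lba_model_spec`.
#' @return named numeric vector of length `spec$k`.
#' @export
natural_to_free <- function(theta, spec) {
  sk <- theta_skeleton(spec)
  if (!all(sk$cell_name %in% names(theta)))
    stop("theta is missing cells: ",
         paste(setdiff(sk$cell_name, names(theta)), collapse = ", "),
         call. = FALSE)
  x <- theta[sk$cell_name]
  x[sk$log_scale] <- log(pmax(x[sk$log_scale], POSITIVE_FLOOR))
  x[!sk$anchored]
}

#' Map a free vector back to the natural scale
#'
#' @param free numeric vector of length `spec$k` (order of [theta_skeleton()]
#'   minus anchored cells).
#' @param spec an `lba_model_spec`.
#' @return named natural-scale vector over all parameter cells (anchored sv
#'   cell included, at 1).
#' @export
free_to_natural <- function(free, spec) {
  sk <- theta_skeleton(spec)
  if (length(free) != sum(!sk$anchored))
    stop("free vector length ", length(free), " != k = ", sum(!sk$anchored),
         call. = FALSE)
  x <- numeric(nrow(sk))
  x[!sk$anchored] <- free
  x[sk$anchored] <- 0  # log(1)
  x[sk$log_scale] <- exp(x[sk$log_scale])
  # anchored cells are sv cells (log scale), so exp(0) = 1 as intended
  setNames(x, sk$cell_name)
}

#' Expand a parameter vector from a nested spec to a finer spec
#'
#' Each cell of the finer spec receives the value of the coarser spec's cell
#' obtained by restricting the factor levels to the coarser spec's factor
#' sets (a parameter fixed across a factor contributes its single value to
#' every level).
#'
#' @param theta named natural-scale vector under `from`.
#' @param from,to `lba_model_spec` objects with `from` nested in `to`
#'   (factor sets of `from` contained in those of `to`, same design).
#' @return named natural-scale vector under `to`.
#' @export
expand_theta <- function(theta, from, to) {
  out <- numeric(0)
  for (type in PARAM_TYPES) {
    ff <- from$factors[[type]]; tf <- to$factors[[type]]
    if (!all(ff %in% tf))
      stop("spec `", from$id, "` is not nested in `", to$id, "` for ", type,
           call. = FALSE)
    fc <- spec_type_cells(from, type)
    tc <- spec_type_cells(to, type)
    if (!length(ff)) {
      idx <- rep(1L, nrow(tc))
    } else {
      key <- function(df) do.call(paste, c(df[ff], sep = "\r"))
      idx <- match(key(tc), key(fc))
    }
    vals <- setNames(theta[fc$cell_name][idx], tc$cell_name)
    out <- c(out, vals)
  }
  out
}

#' Resolve race parameters for one condition cell
#'
#' Maps a model spec and a natural-scale parameter vector to the
#' two-accumulator race of a given design cell (accumulator 1 is the
#' stimulus-matching one). Two cells differing only in factors absent from
#' every parameter type's set receive identical race parameters.
#'
#' @param spec an `lba_model_spec`.
#' @param theta named natural-scale parameter vector (see [theta_skeleton()]).
#' @param cell a `cell_id` from the design's cell table, or a named list of
#'   factor levels identifying one cell.
#' @return an [race_params()] object.
#' @export
resolve_params <- function(spec, theta, cell) {
  design <- spec$design
  if (is.numeric(cell)) {
    cell_id <- as.integer(cell)
  } else {
    sel <- rep(TRUE, nrow(design$cells))
    for (nm in names(cell)) sel <- sel & design$cells[[nm]] == cell[[nm]]
    if (sum(sel) != 1L)
      stop("cell does not identify exactly one design cell", call. = FALSE)
    cell_id <- design$cells$cell_id[sel]
  }
  if (is.na(cell_id) || cell_id < 1L || cell_id > nrow(design$cells))
    stop("unknown cell", call. = FALSE)
  vals <- resolve_rowvalues(spec, theta)
  rows <- c(2L * (cell_id - 1L) + 1L, 2L * (cell_id - 1L) + 2L)
  accs <- lapply(rows, function(r)
    accumulator_params(v = vals$v[r], sv = vals$sv[r], A = vals$A[r],
                       b_minus_A = vals$b_minus_A[r]))
  race_params(accs, correct = 1L, t0 = vals$t0[rows[1]])
}

# Per-paramtab-row natural values for each parameter type.
resolve_rowvalues <- function(spec, theta) {
  sk <- theta_skeleton(spec)
  missing <- setdiff(sk$cell_name, names(theta))
  if (length(missing))
    stop("theta is missing cells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (type in PARAM_TYPES) {
    cells <- spec_type_cells(spec, type)
    idx <- spec_type_index(spec, type)
    out[[type]] <- unname(theta[cells$cell_name][idx])
  }
  out
}

# Precompute the index maps that turn a free parameter vector into per-trial
# race parameters for one participant's trials under a spec. Consumed both by
# the R-level likelihood closure and by the compiled simplex search.
build_loglik_data <- function(trials, spec) {
  design <- spec$design
  keep <- !is.na(trials$rt) & !is.na(trials$correct)
  if (!is.null(trials$response))
    keep <- keep & !is.na(trials$response) & trials$response != "none"
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) stop("empty trial set", call. = FALSE)
  fnames <- names(design$factors)
  missing <- setdiff(fnames, names(trials))
  if (length(missing))
    stop("trials lack design factor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  key <- function(df) do.call(paste, c(df[fnames], sep = "\r"))
  cell_id <- match(key(trials), key(design$cells))
  if (anyNA(cell_id)) {
    bad <- which(is.na(cell_id))[1]
    stop("trial ", bad, " has factor levels matching no design cell",
         call. = FALSE)
  }
  wacc <- ifelse(trials$correct, 1L, 2L)
  wrow <- 2L * (cell_id - 1L) + wacc
  lrow <- 2L * (cell_id - 1L) + (3L - wacc)

  sk <- theta_skeleton(spec)
  offsets <- cumsum(c(0, vapply(PARAM_TYPES, function(type)
    nrow(spec_type_cells(spec, type)), numeric(1))))
  names(offsets) <- c(PARAM_TYPES, "end")
  gidx <- lapply(PARAM_TYPES, function(type)
    offsets[[type]] + spec_type_index(spec, type))
  names(gidx) <- PARAM_TYPES

  rt <- as.numeric(trials$rt)
  list(rt = rt,
       iv_w = as.integer(gidx$v[wrow]), isv_w = as.integer(gidx$sv[wrow]),
       iA_w = as.integer(gidx$A[wrow]), ibA_w = as.integer(gidx$b_minus_A[wrow]),
       iv_l = as.integer(gidx$v[lrow]), isv_l = as.integer(gidx$sv[lrow]),
       iA_l = as.integer(gidx$A[lrow]), ibA_l = as.integer(gidx$b_minus_A[lrow]),
       it0 = as.integer(gidx$t0[wrow]),
       log_scale = sk$log_scale, free_slots = which(!sk$anchored),
       ncells = nrow(sk), n_trials = nrow(trials), min_rt = min(rt))
}

# Fast log-likelihood closure over the free scale (R-level path; the simplex
# search uses the same index data directly in compiled code).
compile_loglik <- function(trials, spec) {
  d <- build_loglik_data(trials, spec)
  fn <- function(free) {
    nat <- numeric(d$ncells)
    nat[d$free_slots] <- free
    nat[d$log_scale] <- exp(nat[d$log_scale])
    Aw <- nat[d$iA_w]; Al <- nat[d$iA_l]
    .lba_loglik2_cpp(d$rt, nat[d$it0],
                     nat[d$iv_w], nat[d$isv_w], Aw, Aw + nat[d$ibA_w],
                     nat[d$iv_l], nat[d$isv_l], Al, Al + nat[d$ibA_l])
  }
  attr(fn, "n_trials") <- d$n_trials
  attr(fn, "min_rt") <- d$min_rt
  attr(fn, "data") <- d
  fn
}
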