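# The paralysis decision system: movement thresholds, the ten binary
# decision models, the per-frame real-time movement rule, session verdicts,
# and scoring (decision percentage, d-prime).
#
# Conventions, resolved conservatively toward NOT declaring paralysis:
# a zone is flagged "low" only when its movement summary is strictly below
# the threshold, and a session is declared paralyzed only when strictly more
# than 90% of its frames are without movement.

#' Movement threshold set
#'
#' @param thresholds named numeric vector of per-zone thresholds (same units
#'   as the Diff summaries they are compared against).
#' @param mode one of `"group_mean_plus_std"`, `"individual_mean"`,
#'   `"two_session_mean"`.
#' @param normalized logical; `TRUE` when thresholds were built from min-max
#'   normalized session summaries.
#' @return An object of class `fapa_thresholds`.
#' @export
threshold_set <- function(thresholds,
                          mode = c("group_mean_plus_std", "individual_mean",
                                   "two_session_mean"),
                          normalized = FALSE) {
  mode <- match.arg(mode)
  if (any(thresholds < 0)) stop("thresholds must be >= 0")
  structure(list(thresholds = thresholds, mode = mode, normalized = normalized),
            class = "fapa_thresholds")
}

# Coerce session summaries to a sessions x zones matrix.
as_summary_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  m <- matrix(as.numeric(x), ncol = 1L)
  colnames(m) <- "Total"
  m
}

#' Group movement threshold: mean + standard deviation
#'
#' Per zone, the threshold is the mean of the per-session Diff summaries plus
#' their sample standard deviation (n - 1).
#'
#' @param session_summaries numeric vector (single zone) or sessions x zones
#'   matrix of Diff means; >= 2 sessions.
#' @param normalized metadata flag recorded on the result.
#' @return A [threshold_set()] in `group_mean_plus_std` mode.
#' @export
group_threshold <- function(session_summaries, normalized = FALSE) {
  m <- as_summary_matrix(session_summaries)
  if (nrow(m) < 2L) stop("insufficient data: group threshold needs >= 2 sessions")
  thr <- colMeans(m) + apply(m, 2L, stats::sd)
  threshold_set(thr, mode = "group_mean_plus_std", normalized = normalized)
}

#' Individual movement threshold: plain mean
#'
#' Per zone, the threshold is the mean of a single mouse's session summaries
#' (no standard-deviation term).
#'
#' @param session_summaries numeric vector or sessions x zones matrix;
#'   >= 1 session.
#' @param normalized metadata flag recorded on the result.
#' @return A [threshold_set()] in `individual_mean` mode.
#' @export
individual_threshold <- function(session_summaries, normalized = FALSE) {
  m <- as_summary_matrix(session_summaries)
  if (nrow(m) < 1L) stop("needs at least one session")
  threshold_set(colMeans(m), mode = "individual_mean", normalized = normalized)
}

#' Two-session movement threshold
#'
#' The minimal design: the average of one baseline session and one paralyzed
#' session, `(Diff(baseline) + Diff(paralyzed)) / 2` per zone. The
#' recommended paralyzed session is the evaluation 24 h after nerve injury.
#'
#' @param diff_baseline,diff_paralyzed per-zone session summaries (named
#'   vectors or scalars), both >= 0.
#' @return A [threshold_set()] in `two_session_mean` mode.
#' @export
two_session_threshold <- function(diff_baseline, diff_paralyzed) {
  if (any(diff_baseline < 0) || any(diff_paralyzed < 0)) {
    stop("session summaries must be >= 0")
  }
  threshold_set((diff_baseline + diff_paralyzed) / 2, mode = "two_session_mean")
}

#' Low-movement binary flags
#'
#' Per zone, flag = 1 iff the session's movement value is strictly below the
#' threshold (a tie is not low).
#'
#' @param session_value named numeric per-zone movement values.
#' @param thresholds a [threshold_set()] covering the same zones.
#' @return Named integer vector of 0/1 flags.
#' @export
low_flags <- function(session_value, thresholds) {
  stopifnot(inherits(thresholds, "fapa_thresholds"))
  thr <- thresholds$thresholds
  if (!is.null(names(session_value)) && !is.null(names(thr))) {
    if (!all(names(session_value) %in% names(thr))) {
      stop("zone mismatch between values and thresholds")
    }
    thr <- thr[names(session_value)]
  } else if (length(session_value) != length(thr)) {
    stop("zone mismatch between values and thresholds")
  }
  stats::setNames(as.integer(session_value < thr), names(session_value))
}

# The ten printed decision models. "or" models flag paralysis when any used
# zone is low; "and" (sum) models only when every used zone is low -- the
# only reading under which the anterior+middle sum model differs from its
# "or" counterpart. Model 10 thresholds the whole uncropped face.
.fapa_models <- list(
  `1`  = list(zones = c("A", "M"),      comb = "or",  scope = "individual"),
  `2`  = list(zones = c("A", "M"),      comb = "and", scope = "group_normalized"),
  `3`  = list(zones = c("A", "M"),      comb = "and", scope = "individual"),
  `4`  = list(zones = c("A", "M"),      comb = "or",  scope = "group"),
  `5`  = list(zones = c("A", "M"),      comb = "and", scope = "group"),
  `6`  = list(zones = c("A", "M", "P"), comb = "or",  scope = "individual"),
  `7`  = list(zones = c("A", "M", "P"), comb = "and", scope = "individual"),
  `8`  = list(zones = c("A", "M", "P"), comb = "or",  scope = "group"),
  `9`  = list(zones = c("A", "M", "P"), comb = "and", scope = "group"),
  `10` = list(zones = "Total",          comb = "and", scope = "group")
)

#' Decision model specification
#'
#' Returns the definition of one of the ten paralysis decision models:
#' which zones it uses, whether it combines them by OR (`"v"`) or by
#' AND-sum (`"+"`), and its threshold scope (group, group-normalized, or
#' individual). Model 2 (anterior + middle, normalized group thresholds) is
#' the recommended default.
#'
#' @param model_id integer 1-10.
#' @return List of class `fapa_model` with `model_id`, `zones`, `comb`,
#'   `scope`.
#' @export
model_spec <- function(model_id) {
  key <- as.character(as.integer(model_id))
  if (!key %in% names(.fapa_models)) stop("unknown model id: ", model_id)
  structure(c(list(model_id = as.integer(model_id)), .fapa_models[[key]]),
            class = "fapa_model")
}

#' Apply a decision model to per-zone low flags
#'
#' @param spec a [model_spec()] (or integer model id).
#' @param flags named 0/1 flags covering the model's zones (from
#'   [low_flags()]).
#' @return A session-level verdict list with `level`, `flags`, `paralyzed`
#'   (logical), and `verdict` (`"paralyzed"` / `"not_paralyzed"`).
#' @export
apply_model <- function(spec, flags) {
  if (!inherits(spec, "fapa_model")) spec <- model_spec(spec)
  if (!all(spec$zones %in% names(flags))) {
    stop("flags do not cover the model's zones: ",
         paste(spec$zones, collapse = ", "))
  }
  used <- flags[spec$zones]
  paralyzed <- if (spec$comb == "or") any(used == 1L) else all(used == 1L)
  list(level = "session", flags = used, paralyzed = paralyzed,
       verdict = if (paralyzed) "paralyzed" else "not_paralyzed")
}

#' Per-frame movement rule
#'
#' The real-time rule: a frame's anterior and middle low flags are summed;
#' a sum below 2 means the mouse is moving, a sum of 2 means it is not.
#'
#' @param flag_A,flag_M binary flags (vectors are evaluated element-wise).
#' @return Logical: `TRUE` when there is movement.
#' @export
frame_movement <- function(flag_A, flag_M) (flag_A + flag_M) < 2

#' Per-frame movement series from Diff values and thresholds
#'
#' Compares per-frame anterior and middle Diff values against the session's
#' zone thresholds and applies the per-frame movement rule.
#'
#' @param diff_A,diff_M per-frame Diff values of the anterior and middle
#'   zones.
#' @param thresholds a [threshold_set()] with zones `A` and `M`.
#' @return Logical movement vector, one element per frame.
#' @export
frame_movement_series <- function(diff_A, diff_M, thresholds) {
  stopifnot(inherits(thresholds, "fapa_thresholds"))
  thr <- thresholds$thresholds
  frame_movement(as.integer(diff_A < thr[["A"]]), as.integer(diff_M < thr[["M"]]))
}

#' Session paralysis verdict from per-frame movements
#'
#' The session is declared paralyzed iff strictly more than 90% of its
#' frames are without movement.
#'
#' @param frame_movements logical movement sequence (>= 1 frame).
#' @param stillness_cutoff strict stillness cutoff (default 0.90).
#' @return List with `level`, `stillness_fraction`, `paralyzed`, `verdict`.
#' @export
session_verdict <- function(frame_movements, stillness_cutoff = 0.90) {
  stopifnot(length(frame_movements) >= 1L)
  stillness <- mean(!frame_movements)
  paralyzed <- stillness > stillness_cutoff
  list(level = "session", stillness_fraction = stillness, paralyzed = paralyzed,
       verdict = if (paralyzed) "paralyzed" else "not_paralyzed")
}

#' Run a decision model over a timeline of session summaries
#'
#' Builds the thresholds, flags each session's zones, and applies the model,
#' producing one verdict per session.
#'
#' @param summaries sessions x zones matrix of Diff means with column names
#'   covering the model's zones (plus `Total` for model 10).
#' @param model model id 1-10 (default 2) or a [model_spec()].
#' @param threshold_mode `"two_session"` (default), `"group"` (mean + sd,
#'   min-max normalized first when the model's scope asks for it), or
#'   `"individual"` (plain mean).
#' @param baseline,paralyzed session row indices feeding the two-session
#'   threshold (defaults: session 1 = baseline, session 4 = 24 h
#'   post-injury).
#' @param anchor optional sessions x zones summary matrix of a reference
#'   mouse with verified paralysis (e.g. a transection timeline) from which
#'   the thresholds are built instead of the evaluated mouse's own data; the
#'   two-session threshold is only meaningful when its `paralyzed` session
#'   really is still, so an uninjured mouse must be scored against an
#'   injured reference.
#' @return List with `paralyzed` (logical per session), `flags` (sessions x
#'   zones), `thresholds`, and `model`.
#' @export
infer_timeline <- function(summaries, model = 2,
                           threshold_mode = c("two_session", "group", "individual"),
                           baseline = 1L, paralyzed = 4L, anchor = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  spec <- if (inherits(model, "fapa_model")) model else model_spec(model)
  m <- as_summary_matrix(summaries)
  if (!all(spec$zones %in% colnames(m))) {
    stop("summary matrix lacks the model's zones: ",
         paste(spec$zones, collapse = ", "))
  }
  m <- m[, spec$zones, drop = FALSE]
  ref <- if (is.null(anchor)) m else {
    a <- as_summary_matrix(anchor)
    if (!all(spec$zones %in% colnames(a))) {
      stop("anchor matrix lacks the model's zones")
    }
    a[, spec$zones, drop = FALSE]
  }
  normalized <- threshold_mode == "group" && spec$scope == "group_normalized"
  if (normalized) {
    m <- apply(m, 2L, normalize_sessions)
    ref <- if (is.null(anchor)) m else apply(ref, 2L, normalize_sessions)
  }
  ts <- switch(threshold_mode,
               two_session = two_session_threshold(ref[baseline, ], ref[paralyzed, ]),
               group = group_threshold(ref, normalized = normalized),
               individual = individual_threshold(ref, normalized = normalized))
  flags <- t(apply(m, 1L, low_flags, thresholds = ts))
  colnames(flags) <- spec$zones
  verdicts <- apply(flags, 1L, function(f) apply_model(spec, f)$paralyzed)
  list(paralyzed = as.logical(verdicts), flags = flags, thresholds = ts,
       model = spec)
}

#' Decision percentage of the paralysis detector
#'
#' The percentage of truly paralyzed days (ground truth from the whisker
#' analysis) on which the system also declares paralysis.
#'
#' @param verdicts logical (or 0/1) per-day system verdicts.
#' @param ground_truth logical per-day paralysis labels, same length.
#' @return Percentage in `[0, 100]`.
#' @export
decision_percentage <- function(verdicts, ground_truth) {
  verdicts <- as.logical(verdicts); ground_truth <- as.logical(ground_truth)
  if (length(verdicts) != length(ground_truth)) {
    stop("verdicts and ground truth must cover the same days")
  }
  if (!any(ground_truth)) stop("undefined metric: no truly paralyzed days")
  100 * sum(verdicts & ground_truth) / sum(ground_truth)
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with the inverse-normal
#' transform; extreme rates of 0 or 1 are corrected by the 1/(2N) rule
#' before transforming. The conventional operand order (hits first) is used,
#' so a good detector scores positive.
#'
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @param n_trials trial count behind each rate; required when either rate
#'   is exactly 0 or 1.
#' @return Scalar sensitivity.
#' @export
d_prime <- function(hit_rate, fa_rate, n_trials = NULL) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  fix <- function(r) {
    if (r > 0 && r < 1) return(r)
    if (is.null(n_trials) || n_trials < 1) {
      stop("n_trials is required to correct an extreme rate of ", r)
    }
    if (r <= 0) 1 / (2 * n_trials) else 1 - 1 / (2 * n_trials)
  }
  stats::qnorm(fix(hit_rate)) - stats::qnorm(fix(fa_rate))
}
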