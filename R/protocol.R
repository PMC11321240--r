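#' Actuator drum angular speed used for every pull (rad/s)
#'
#' All actuator rotation sequences use the same constant drum speed; conditions
#' differ only in pull direction, duration, and trigger delay policy.
#' @export
PULL_ANGULAR_SPEED <- 40

#' Default actuator drum radius (m)
#'
#' Radius of the rope drum on the tethered actuator. At the fixed drum speed
#' of 40 rad/s this radius gives a rope retraction speed of about 0.79 m/s.
#' @export
DRUM_RADIUS <- 0.01975

#' Rope retraction speed for a drum rotation
#'
#' @param angular_speed drum angular speed in rad/s.
#' @param radius drum radius in m.
#' @return linear rope speed in m/s.
#' @examples
#' rope_speed() # ~0.79 m/s at the defaults
#' @export
rope_speed <- function(angular_speed = PULL_ANGULAR_SPEED, radius = DRUM_RADIUS) {
  angular_speed * radius
}

CONDITION_NAMES <- c("control", "rapid_assist", "delayed_assist",
                     "rapid_perturb", "delayed_perturb", "passive")

#' Experimental condition specifications
#'
#' Returns the six experimental conditions of the arm-extension protocol as a
#' data frame, one row per condition:
#' \describe{
#'   \item{control}{voluntary extension, no actuator pull.}
#'   \item{rapid_assist / delayed_assist}{0.31 s pull in the extension
#'     direction, released at the detector trigger (rapid) or 40 ms after it
#'     (delayed).}
#'   \item{rapid_perturb / delayed_perturb}{0.10 s pull opposing extension,
#'     with the same two delay policies.}
#'   \item{passive}{assistive pull with the participant instructed not to
#'     contract; no voluntary burst.}
#' }
#'
#' @return data frame with columns `name`, `direction` (+1 extension /
#'   assist, -1 flexion / perturb, 0 none), `pull_duration` (s),
#'   `artificial_delay` (s) and `voluntary` (logical).
#' @export
condition_specs <- function() {
  data.frame(
    name = CONDITION_NAMES,
    direction = c(0L, 1L, 1L, -1L, -1L, 1L),
    pull_duration = c(0, 0.31, 0.31, 0.10, 0.10, 0.31),
    artificial_delay = c(0, 0, 0.040, 0, 0.040, 0),
    voluntary = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Look up a single condition specification
#'
#' @param name one of `"control"`, `"rapid_assist"`, `"delayed_assist"`,
#'   `"rapid_perturb"`, `"delayed_perturb"`, `"passive"`.
#' @return one-row data frame (see [condition_specs()]).
#' @export
condition_spec <- function(name) {
  specs <- condition_specs()
  i <- match(name, specs$name)
  if (is.na(i)) {
    stop("unknown condition '", name, "'; expected one of: ",
         paste(specs$name, collapse = ", "), call. = FALSE)
  }
  specs[i, , drop = FALSE]
}

#' Build the session schedule for one participant
#'
#' Each condition is a block of 50 cued arm extensions: 10 without a pull
#' (`pre`), 30 with a pull (`pulled`; the control block keeps the phase label
#' but never receives a pull), and 10 without (`post`). The order of the five
#' non-passive blocks is a uniform random permutation; the passive block, if
#' included, always comes last. Successive cues are separated by independent
#' uniform draws on [5, 15] s.
#'
#' @param participant_id identifier stored in the plan.
#' @param include_passive append the passive block after the five randomized
#'   blocks (default `FALSE`).
#' @param seed optional integer; when given, the schedule is drawn from a
#'   private RNG stream seeded with it (the caller's RNG state is untouched).
#'   When `NULL`, draws come from the current RNG state.
#' @return data frame of class `session_plan`: one row per trial with columns
#'   `participant`, `trial`, `block`, `order_position` (1-based position of
#'   the trial's block in the session), `condition`, `phase`
#'   (`pre`/`pulled`/`post`) and `cue_time` (s since session start).
#' @examples
#' plan <- schedule_session("P01", seed = 1)
#' nrow(plan) # 250
#' @export
schedule_session <- function(participant_id = "P01", include_passive = FALSE,
                             seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  order5 <- sample(CONDITION_NAMES[1:5])
  blocks <- if (include_passive) c(order5, "passive") else order5
  n_blocks <- length(blocks)
  phase <- rep(c("pre", "pulled", "post"), times = c(10L, 30L, 10L))
  n <- 50L * n_blocks
  gaps <- stats::runif(n, 5, 15)
  plan <- data.frame(
    participant = participant_id,
    trial = seq_len(n),
    block = rep(seq_len(n_blocks), each = 50L),
    order_position = rep(seq_len(n_blocks), each = 50L),
    condition = rep(blocks, each = 50L),
    phase = rep(phase, times = n_blocks),
    cue_time = cumsum(gaps),
    stringsAsFactors = FALSE
  )
  class(plan) <- c("session_plan", "data.frame")
  plan
}

#' Pull command for a triggered condition
#'
#' Converts a detector trigger into the actuator rotation command for the
#' trial's condition: the pull starts at the trigger time plus the condition's
#' artificial delay (0 for rapid, 40 ms for delayed) and runs at the fixed
#' drum speed for the condition's duration in the condition's direction.
#'
#' @param spec one-row condition specification (see [condition_spec()]).
#' @param trigger_time detector trigger time in seconds (>= 0).
#' @return list with `start_time`, `duration`, `angular_speed`, `direction`,
#'   or `NULL` for an unpulled (control) condition.
#' @export
make_pull_command <- function(spec, trigger_time) {
  stopifnot(is.numeric(trigger_time), length(trigger_time) == 1L,
            trigger_time >= 0)
  if (spec$direction == 0L) return(NULL)
  list(
    start_time = trigger_time + spec$artificial_delay,
    duration = spec$pull_duration,
    angular_speed = PULL_ANGULAR_SPEED,
    direction = as.integer(spec$direction)
  )
}

#' Write / read a session plan as a tabular text file
#'
#' @param plan a `session_plan` data frame.
#' @param path file path.
#' @return `read_session_plan` returns the plan; `write_session_plan` returns
#'   `path` invisibly.
#' @export
write_session_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_plan
#' @export
read_session_plan <- function(path) {
  plan <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(plan) <- c("session_plan", "data.frame")
  plan
}
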