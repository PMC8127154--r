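#' Oddball paradigm configuration
#'
#' Describes an auditory oddball run: frequent Standard tones interleaved with
#' rare Deviant and Novel tones on a fixed slot grid, interrupted by silent
#' rest blocks, with the Standard/Deviant tone identities swapped halfway
#' through the run to counter habituation.
#'
#' Tones occupy slots of period \code{tone_duration + isi} (0.705 s by
#' default). Defaults follow the task design: tone probabilities
#' .84/.09/.07 (Standard/Deviant/Novel), 80 ms tones, 625 ms inter-stimulus
#' interval, five initial Standard tones, at least three Standard tones
#' between non-standard onsets, six evenly distributed 10 s rest blocks, and
#' an initial silence of ten repetition times.
#'
#' @param p_deviant,p_novel,p_standard tone-type probabilities; must sum to 1.
#' @param tone_duration tone duration in seconds.
#' @param isi inter-stimulus interval in seconds.
#' @param n_initial_standards number of forced Standard tones at run start.
#' @param min_standards_between minimum Standard tones between consecutive
#'   non-standard (Deviant or Novel) onsets.
#' @param n_rest_blocks number of silent rest blocks.
#' @param rest_duration rest block duration in seconds.
#' @param initial_silence initial silent period in seconds (defaults to ten
#'   volumes of the multi-echo radial arm, 10 x 2.648 s).
#' @param total_duration run duration in seconds.
#' @param swap_at_half swap Standard/Deviant tone identities at the midpoint
#'   tone index?
#' @param swap_pauses_stream does the swap cue pause the tone stream for one
#'   slot period (TRUE) or occupy no time (FALSE)?
#' @param seed default RNG seed for schedule generation.
#' @return An object of class \code{paradigm_config}.
#' @export
paradigm_config <- function(p_deviant = 0.09, p_novel = 0.07,
                            p_standard = 0.84,
                            tone_duration = 0.08, isi = 0.625,
                            n_initial_standards = 5L,
                            min_standards_between = 3L,
                            n_rest_blocks = 6L, rest_duration = 10,
                            initial_silence = 10 * 2.648,
                            total_duration = 635,
                            swap_at_half = TRUE,
                            swap_pauses_stream = TRUE,
                            seed = 1L) {
  cfg <- list(p_deviant = p_deviant, p_novel = p_novel,
              p_standard = p_standard,
              tone_duration = tone_duration, isi = isi,
              n_initial_standards = as.integer(n_initial_standards),
              min_standards_between = as.integer(min_standards_between),
              n_rest_blocks = as.integer(n_rest_blocks),
              rest_duration = rest_duration,
              initial_silence = initial_silence,
              total_duration = total_duration,
              swap_at_half = isTRUE(swap_at_half),
              swap_pauses_stream = isTRUE(swap_pauses_stream),
              seed = as.integer(seed))
  class(cfg) <- "paradigm_config"
  validate_paradigm_config(cfg)
  cfg
}

validate_paradigm_config <- function(cfg) {
  psum <- cfg$p_deviant + cfg$p_novel + cfg$p_standard
  if (abs(psum - 1) > 1e-9)
    stop("tone-type probabilities must sum to 1 (got ", psum, ")")
  if (any(c(cfg$p_deviant, cfg$p_novel, cfg$p_standard) < 0))
    stop("tone-type probabilities must be nonnegative")
  if (cfg$min_standards_between < 0L)
    stop("min_standards_between must be >= 0")
  q <- cfg$p_deviant + cfg$p_novel
  if (q > 1 / (cfg$min_standards_between + 1) + 1e-12)
    stop("infeasible paradigm: p_deviant + p_novel = ", q,
         " exceeds 1/(min_standards_between+1) = ",
         1 / (cfg$min_standards_between + 1),
         "; the spacing constraint cannot sustain these probabilities")
  if (cfg$tone_duration <= 0 || cfg$isi < 0)
    stop("tone_duration must be positive and isi nonnegative")
  if (cfg$total_duration <= cfg$initial_silence)
    stop("total_duration must exceed initial_silence")
  invisible(cfg)
}

# Draw tone types for up to n slots. Eligible slots draw non-standard with the
# adjusted probability q* = q / (1 - m q): the renewal process of one
# non-standard onset followed by m forced Standards then geometric waiting has
# stationary non-standard fraction exactly q, so realized fractions converge
# to the configured probabilities.
draw_tone_types <- function(n, cfg) {
  q <- cfg$p_deviant + cfg$p_novel
  m <- cfg$min_standards_between
  qstar <- if (q <= 0) 0 else q / (1 - m * q)
  qstar <- min(qstar, 1)
  types <- character(n)
  since_ns <- Inf  # standards since last non-standard
  for (i in seq_len(n)) {
    if (i <= cfg$n_initial_standards || since_ns < m) {
      types[i] <- "standard"
      since_ns <- since_ns + 1
    } else if (stats::runif(1) < qstar) {
      types[i] <- if (stats::runif(1) < cfg$p_deviant / q) "deviant" else "novel"
      since_ns <- 0
    } else {
      types[i] <- "standard"
      since_ns <- since_ns + 1
    }
  }
  types
}

# Lay out events on the slot grid. types: pre-drawn slot types; swap_after:
# tone index after which a one-slot pause (swap cue) is inserted, or NA.
layout_events <- function(types, cfg, swap_after = NA) {
  slot <- cfg$tone_duration + cfg$isi
  span <- (cfg$total_duration - cfg$initial_silence) / (cfg$n_rest_blocks + 1)
  rest_times <- cfg$initial_silence + seq_len(cfg$n_rest_blocks) * span
  onset <- numeric(0); duration <- numeric(0)
  trial_type <- character(0); tone_id <- character(0)
  t <- cfg$initial_silence
  rest_i <- 1L
  tone_i <- 0L
  swap_time <- NA_real_
  swapped <- FALSE
  novel_i <- 0L
  repeat {
    if (rest_i <= cfg$n_rest_blocks && t >= rest_times[rest_i] - 1e-9) {
      if (t + cfg$rest_duration > cfg$total_duration) break
      onset <- c(onset, t); duration <- c(duration, cfg$rest_duration)
      trial_type <- c(trial_type, "rest"); tone_id <- c(tone_id, "rest")
      t <- t + cfg$rest_duration
      rest_i <- rest_i + 1L
      next
    }
    if (!is.na(swap_after) && tone_i == swap_after && !swapped) {
      swapped <- TRUE
      swap_time <- t
      onset <- c(onset, t)
      duration <- c(duration, if (cfg$swap_pauses_stream) slot else 0)
      trial_type <- c(trial_type, "swap_cue"); tone_id <- c(tone_id, "swap")
      if (cfg$swap_pauses_stream) t <- t + slot
      next
    }
    if (t + slot > cfg$total_duration + 1e-9) break
    tone_i <- tone_i + 1L
    if (tone_i > length(types)) break
    ty <- types[tone_i]
    id <- switch(ty,
      standard = if (swapped) "tone_B" else "tone_A",
      deviant  = if (swapped) "tone_A" else "tone_B",
      novel = { novel_i <- novel_i + 1L; sprintf("novel_%03d", novel_i) })
    onset <- c(onset, t); duration <- c(duration, cfg$tone_duration)
    trial_type <- c(trial_type, ty); tone_id <- c(tone_id, id)
    t <- t + slot
  }
  list(events = data.frame(onset = onset, duration = duration,
                           trial_type = trial_type, tone_id = tone_id,
                           stringsAsFactors = FALSE),
       n_tones = tone_i, swap_time = swap_time)
}

#' Generate an oddball event schedule
#'
#' Places tones on the slot grid defined by the configuration, enforcing the
#' initial run of Standard tones and the minimum number of Standard tones
#' between non-standard onsets, inserting evenly spaced silent rest blocks,
#' and (optionally) a swap cue at the midpoint tone index where the Standard
#' and Deviant tone identities exchange roles.
#'
#' @param config a \code{\link{paradigm_config}}.
#' @param seed RNG seed; defaults to the seed stored in \code{config}.
#' @return An object of class \code{oddball_schedule}: a list with elements
#'   \code{events} (data frame with columns onset, duration, trial_type,
#'   tone_id), \code{config}, \code{swap_time} and \code{n_tones}.
#' @export
generate_schedule <- function(config, seed = config$seed) {
  validate_paradigm_config(config)
  # upper bound on slot count (no rests, no pause)
  slot <- config$tone_duration + config$isi
  n_max <- ceiling((config$total_duration - config$initial_silence) / slot) + 2L
  set.seed(seed)
  types <- draw_tone_types(n_max, config)
  pass1 <- layout_events(types, config, swap_after = NA)
  swap_after <- if (config$swap_at_half) pass1$n_tones %/% 2L else NA
  out <- if (config$swap_at_half)
    layout_events(types, config, swap_after = swap_after) else pass1
  sched <- list(events = out$events, config = config,
                swap_time = out$swap_time, n_tones = out$n_tones,
                swap_index = if (config$swap_at_half) swap_after else NA)
  class(sched) <- "oddball_schedule"
  sched
}

#' @export
print.oddball_schedule <- function(x, ...) {
  tt <- x$events$trial_type
  cat("oddball_schedule:", x$n_tones, "tones (",
      sum(tt == "standard"), "standard,", sum(tt == "deviant"), "deviant,",
      sum(tt == "novel"), "novel ),", sum(tt == "rest"), "rest blocks;",
      "swap at", ifelse(is.na(x$swap_time), "none", format(x$swap_time)),
      "s\n")
  invisible(x)
}

#' Validate an oddball schedule against its design rules
#'
#' Checks every schedule invariant and returns a report instead of throwing:
#' initial Standards, non-standard spacing, rest-block count and duration,
#' non-overlap, nonnegative onsets, and uniqueness of Novel tone identifiers.
#'
#' @param schedule an \code{oddball_schedule}.
#' @return A data frame with columns \code{rule}, \code{index} and
#'   \code{message}; zero rows when the schedule is valid.
#' @export
validate_schedule <- function(schedule) {
  ev <- schedule$events
  cfg <- schedule$config
  viol <- list()
  add <- function(rule, index, msg)
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, index = index,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  if (any(ev$onset < 0))
    add("nonnegative_onset", which(ev$onset < 0)[1], "negative onset")
  o <- order(ev$onset)
  ends <- ev$onset[o] + ev$duration[o]
  if (nrow(ev) > 1) {
    ov <- which(ev$onset[o][-1] < ends[-length(ends)] - 1e-9)
    if (length(ov)) add("non_overlap", o[ov[1] + 1], "overlapping events")
  }
  tones <- ev[ev$trial_type %in% c("standard", "deviant", "novel"), ]
  if (!is.null(cfg)) {
    k <- cfg$n_initial_standards
    if (nrow(tones) >= k && any(tones$trial_type[seq_len(k)] != "standard"))
      add("initial_standards",
          which(tones$trial_type[seq_len(k)] != "standard")[1],
          sprintf("first %d tones must be standard", k))
    ns <- which(tones$trial_type != "standard")
    if (length(ns) > 1) {
      gaps <- diff(ns) - 1L
      bad <- which(gaps < cfg$min_standards_between)
      if (length(bad))
        add("non_standard_spacing", ns[bad[1] + 1],
            sprintf("fewer than %d standard tones between non-standard onsets",
                    cfg$min_standards_between))
    }
    rests <- ev[ev$trial_type == "rest", ]
    if (nrow(rests) != cfg$n_rest_blocks)
      add("rest_block_count", NA_integer_,
          sprintf("expected %d rest blocks, found %d", cfg$n_rest_blocks,
                  nrow(rests)))
    if (nrow(rests) && any(abs(rests$duration - cfg$rest_duration) > 1e-9))
      add("rest_block_duration", which(ev$trial_type == "rest")[1],
          "rest block duration differs from configuration")
  }
  nov <- ev$tone_id[ev$trial_type == "novel"]
  if (anyDuplicated(nov))
    add("novel_id_unique", which(ev$trial_type == "novel")[1],
        "duplicate novel tone identifiers")
  if (length(viol)) do.call(rbind, viol)
  else data.frame(rule = character(0), index = integer(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Write / read a schedule as a BIDS-style events table
#'
#' Serializes the event list to a tab-separated table with columns
#' \code{onset}, \code{duration}, \code{trial_type}, \code{tone_id}.
#' Numeric fields are written with 17 significant digits so the round trip
#' reproduces onsets and durations exactly.
#'
#' @param schedule an \code{oddball_schedule}.
#' @param path file path of the events TSV.
#' @return \code{write_events} returns \code{path} invisibly;
#'   \code{read_events} returns an \code{oddball_schedule} (with
#'   \code{config = NULL} since the table does not carry the configuration).
#' @export
write_events <- function(schedule, path) {
  ev <- schedule$events
  df <- data.frame(onset = sprintf("%.17g", ev$onset),
                   duration = sprintf("%.17g", ev$duration),
                   trial_type = ev$trial_type, tone_id = ev$tone_id,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("events table is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!("tone_id" %in% names(df))) df$tone_id <- NA_character_
  if (!is.numeric(df$onset) || !is.numeric(df$duration))
    stop("events table: onset and duration must be numeric")
  if (any(df$onset < 0))
    stop("parse error at line ", which(df$onset < 0)[1] + 1L,
         ": negative onset")
  tones <- df$trial_type %in% c("standard", "deviant", "novel")
  sched <- list(events = df[, c("onset", "duration", "trial_type", "tone_id")],
                config = NULL,
                swap_time = if (any(df$trial_type == "swap_cue"))
                  df$onset[df$trial_type == "swap_cue"][1] else NA_real_,
                n_tones = sum(tones))
  class(sched) <- "oddball_schedule"
  sched
}
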