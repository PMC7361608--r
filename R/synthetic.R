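#' Default item battery for synthetic cohorts
#'
#' Eleven trust-in-institutions attitude items on a 1--4 scale (four of
#' which are contested between the planted factions by default), three
#' behavioural-compliance and three epistemic-clarity items on 1--7 scales,
#' and one 1--7 attention-check item.
#'
#' @return Named list of [item_spec()] objects.
#' @export
default_cohort_items <- function() {
  s4 <- likert_scale(1, 4)
  s7 <- likert_scale(1, 7)
  trust <- c("trust_science", "trust_scientists", "trust_government",
             "trust_doctors", "trust_journalists", "trust_charity_workers",
             "trust_traditional_healers", "trust_community", "trust_vaccines",
             "trust_health_advice", "trust_nurses")
  items <- c(
    lapply(trust, function(id) item_spec(id, scale = s4, block = "attitude")),
    lapply(paste0("compliance_", 1:3), function(id)
      item_spec(id, scale = s7, block = "compliance")),
    lapply(paste0("clarity_", 1:3), function(id)
      item_spec(id, scale = s7, block = "clarity")),
    list(item_spec("attention_check", scale = s7, block = "attention"))
  )
  as_item_list(items)
}

#' Configuration for the synthetic two-faction cohort
#'
#' Defines the planted structure the generator emulates: two latent factions
#' of fixed membership, a block of shared (consensus) attitude items on
#' which both factions lean positive, and a block of contested items on
#' which faction 1 drifts negative at a per-wave rate `d_t` (the divergence
#' schedule), producing an attitudinal schism that grows across waves.
#'
#' @param n_participants Cohort size at wave 1.
#' @param faction_fractions Two positive fractions summing to 1; faction
#'   sizes are the rounded counts.
#' @param n_waves Number of waves.
#' @param consensus_strength Probability `c` in `[0.5, 1]` that a
#'   respondent's stance sign matches their (drawn) template sign.
#' @param divergence_schedule Numeric vector, one `d_t` in `[0, 1]` per
#'   wave: the probability that a faction-1 respondent's template on a
#'   contested item is negative at wave `t`.
#' @param attrition_rate Per-wave dropout probability (applied from wave 2;
#'   dropout is permanent).
#' @param attention_fail_rate Probability a respondent fails the
#'   attention check in a given wave.
#' @param neutral_rate Probability that a non-template-matching stance falls
#'   in the neutral region instead of the opposite half; inert on scales
#'   with no attainable midpoint (such as the default 1--4 trust items).
#' @param outcome_effect_d Cohen's d by which faction 1's compliance and
#'   clarity scale scores sit below faction 0's.
#' @param items Item battery (see [default_cohort_items()]).
#' @param contested_items Ids of the contested attitude items.
#' @param attention_expected Correct attention-check response.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 300,
                          faction_fractions = c(0.6, 0.4),
                          n_waves = 3,
                          consensus_strength = 0.85,
                          divergence_schedule = c(0.2, 0.5, 0.9),
                          attrition_rate = 0.05,
                          attention_fail_rate = 0.01,
                          neutral_rate = 0.1,
                          outcome_effect_d = 0.3,
                          items = default_cohort_items(),
                          contested_items = c("trust_science",
                                              "trust_scientists",
                                              "trust_government",
                                              "trust_journalists"),
                          attention_expected = 4L,
                          seed = 20200309L) {
  items <- as_item_list(items)
  stopifnot(length(faction_fractions) == 2L)
  if (any(faction_fractions <= 0) || abs(sum(faction_fractions) - 1) > 1e-8) {
    stop("faction fractions must be positive and sum to 1", call. = FALSE)
  }
  sizes <- c(round(n_participants * faction_fractions[1]), 0L)
  sizes[2] <- n_participants - sizes[1]
  if (any(sizes < 1L)) stop("each faction needs at least one participant", call. = FALSE)
  if (length(divergence_schedule) != n_waves) {
    stop("divergence_schedule needs one entry per wave", call. = FALSE)
  }
  probs <- c(consensus_strength, divergence_schedule, attrition_rate,
             attention_fail_rate, neutral_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (consensus_strength < 0.5) {
    stop("consensus_strength below 0.5 inverts the planted structure", call. = FALSE)
  }
  attitude <- names(items)[vapply(items, `[[`, character(1), "block") == "attitude"]
  if (!all(contested_items %in% attitude)) {
    stop("contested_items must be attitude items", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         faction_sizes = as.integer(sizes),
         faction_fractions = faction_fractions,
         n_waves = as.integer(n_waves),
         consensus_strength = consensus_strength,
         divergence_schedule = divergence_schedule,
         attrition_rate = attrition_rate,
         attention_fail_rate = attention_fail_rate,
         neutral_rate = neutral_rate,
         outcome_effect_d = outcome_effect_d,
         items = items,
         attitude_items = attitude,
         contested_items = contested_items,
         shared_items = setdiff(attitude, contested_items),
         attention_expected = as.integer(attention_expected),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_config: n=%d (factions %d/%d), %d waves, c=%.2f, d=(%s),\n",
    "  %d attitude items (%d contested), attrition %.2f/wave, seed %d>\n"),
    x$n_participants, x$faction_sizes[1], x$faction_sizes[2], x$n_waves,
    x$consensus_strength, paste(x$divergence_schedule, collapse = ", "),
    length(x$attitude_items), length(x$contested_items),
    x$attrition_rate, x$seed))
  invisible(x)
}

# sample integer responses for given stance signs on one likert scale:
# +1 -> uniform over values above the midpoint, -1 -> below, 0 -> midpoint
sample_half_scale <- function(sign, scale) {
  pos <- seq.int(floor(scale$midpoint) + 1L, scale$max)
  neg <- seq.int(scale$min, ceiling(scale$midpoint) - 1L)
  out <- integer(length(sign))
  np <- sum(sign == 1L); nn <- sum(sign == -1L); nz <- sum(sign == 0L)
  if (np) out[sign == 1L] <- sample(pos, np, replace = TRUE)
  if (nn) out[sign == -1L] <- sample(neg, nn, replace = TRUE)
  if (nz) {
    if (!has_midpoint(scale)) stop("neutral stance on a scale without midpoint")
    out[sign == 0L] <- as.integer(scale$midpoint)
  }
  out
}

# likert-ize a latent gaussian onto [1, 7]-style scales
round_clamp <- function(x, scale) {
  as.integer(pmin(pmax(round(x), scale$min), scale$max))
}

#' Generate a synthetic longitudinal cohort with a planted schism
#'
#' Draws `n_waves` of Likert responses for a panel with two latent factions.
#' Shared attitude items carry a positive template for everyone; contested
#' items carry a positive template for faction 0 while each faction-1
#' respondent's template is negative with probability `d_t`, so the
#' between-faction stance gap ramps with the divergence schedule. Each
#' stance sign matches its template with probability `c`
#' (`consensus_strength`), falls in the neutral region with probability
#' `(1-c) * neutral_rate` when the scale has an attainable midpoint, and is
#' opposite otherwise; the integer response is uniform over the
#' template-consistent half of the scale. Compliance and clarity items are
#' generated from a person-level latent score (between-person SD chosen so
#' scale reliability lands near the 0.7--0.8 typical of short batteries)
#' with faction 1 shifted down by `outcome_effect_d` standard deviations of
#' the scale score. Wave-on-wave attrition is permanent; attention-check
#' failures are planted at `attention_fail_rate`. Everything is reproducible
#' from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with `waves` (list of [response_matrix()], attrited
#'   participants absent) and `truth` (ground truth: `faction_of`, named
#'   0/1 integer vector; `templates`, per-wave matrices of drawn template
#'   signs for the attitude items; `faction_template`, per-wave 2 x items
#'   expected-sign matrices; `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  faction <- rep(0:1, config$faction_sizes)
  names(faction) <- ids

  att_ids <- config$attitude_items
  m <- length(att_ids)
  contested <- att_ids %in% config$contested_items
  c_str <- config$consensus_strength

  # person-level latent outcome scores, fixed across waves
  outcome_latent <- function(sd_b, shift) {
    stats::rnorm(n, mean = 0, sd = sd_b) - shift * (faction == 1)
  }
  # compliance: item = latent + e, sd_b = 0.9, sd_e = 1.0 -> alpha ~ .71;
  # scale-score sd = sqrt(sd_b^2 + sd_e^2/3)
  comp_scale_sd <- sqrt(0.9^2 + 1.0^2 / 3)
  clar_scale_sd <- sqrt(0.55^2 + 0.6^2 / 3)
  comp_lat <- 5.7 + outcome_latent(0.9, config$outcome_effect_d * comp_scale_sd)
  clar_lat <- 6.3 + outcome_latent(0.55, config$outcome_effect_d * clar_scale_sd)

  present <- rep(TRUE, n)
  waves <- vector("list", config$n_waves)
  templates <- vector("list", config$n_waves)
  faction_template <- vector("list", config$n_waves)

  for (t in seq_len(config$n_waves)) {
    if (t > 1L) present <- present & (stats::runif(n) >= config$attrition_rate)
    d_t <- config$divergence_schedule[t]

    # template signs: shared +1 everywhere; contested: faction 1 negative w.p. d_t
    tmpl <- matrix(1L, n, m, dimnames = list(ids, att_ids))
    f1 <- faction == 1
    if (any(contested) && any(f1)) {
      flip <- matrix(stats::runif(sum(f1) * sum(contested)) < d_t,
                     sum(f1), sum(contested))
      tmpl[f1, contested][flip] <- -1L
    }

    # stance signs: match template w.p. c, else neutral w.p. neutral_rate
    # (only on scales with an attainable midpoint), else opposite
    stance <- tmpl
    miss <- matrix(stats::runif(n * m) >= c_str, n, m)
    neut <- matrix(stats::runif(n * m) < config$neutral_rate, n, m)
    scales4 <- lapply(config$items[att_ids], `[[`, "scale")
    mid_ok <- vapply(scales4, has_midpoint, logical(1))
    neut <- sweep(neut, 2, mid_ok, `&`)
    stance[miss & neut] <- 0L
    stance[miss & !neut] <- -tmpl[miss & !neut]

    # integer responses per item (columns share scales, may differ)
    vals <- matrix(NA_integer_, n, length(config$items),
                   dimnames = list(ids, names(config$items)))
    for (j in seq_along(att_ids)) {
      vals[, att_ids[j]] <- sample_half_scale(stance[, j], scales4[[j]])
    }
    for (j in 1:3) {
      vals[, paste0("compliance_", j)] <-
        round_clamp(comp_lat + stats::rnorm(n, sd = 1.0),
                    config$items[[paste0("compliance_", j)]]$scale)
      vals[, paste0("clarity_", j)] <-
        round_clamp(clar_lat + stats::rnorm(n, sd = 0.6),
                    config$items[[paste0("clarity_", j)]]$scale)
    }
    att_scale <- config$items[["attention_check"]]$scale
    att_resp <- rep(config$attention_expected, n)
    fails <- stats::runif(n) < config$attention_fail_rate
    if (any(fails)) {
      wrong <- setdiff(seq.int(att_scale$min, att_scale$max),
                       config$attention_expected)
      att_resp[fails] <- sample(wrong, sum(fails), replace = TRUE)
    }
    vals[, "attention_check"] <- att_resp

    waves[[t]] <- response_matrix(vals[present, , drop = FALSE], config$items,
                                  ids[present], paste0("T", t))
    templates[[t]] <- tmpl[present, , drop = FALSE]
    ft <- rbind(rep(1, m), ifelse(contested, 1 - 2 * d_t, 1))
    dimnames(ft) <- list(c("faction0", "faction1"), att_ids)
    faction_template[[t]] <- ft
  }

  truth <- structure(
    list(faction_of = faction, templates = templates,
         faction_template = faction_template, config = config),
    class = "cohort_truth"
  )
  list(waves = waves, truth = truth)
}

#' Summarize a synthetic cohort against its ground truth
#'
#' @param waves List of [response_matrix()] from [generate_cohort()].
#' @param truth Matching `cohort_truth`.
#' @return List of data frames: `overview` (per wave: n, faction sizes,
#'   mean between-faction stance gap on contested items) and `consensus`
#'   (per wave, item and faction: fraction of stances matching the drawn
#'   template).
#' @export
cohort_summary <- function(waves, truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  cfg <- truth$config
  overview <- NULL
  consensus <- NULL
  for (t in seq_along(waves)) {
    w <- waves[[t]]
    tmpl <- truth$templates[[t]]
    if (!identical(rownames(tmpl), w$participants)) {
      stop(sprintf("wave %d participant ids do not match ground truth", t),
           call. = FALSE)
    }
    st <- binarize(subset_items(w, cfg$attitude_items))
    f <- truth$faction_of[w$participants]
    gap_items <- cfg$contested_items
    gap <- mean(colMeans(st$stances[f == 0, gap_items, drop = FALSE], na.rm = TRUE) -
                colMeans(st$stances[f == 1, gap_items, drop = FALSE], na.rm = TRUE))
    overview <- rbind(overview, data.frame(
      wave = w$wave_id, n = length(f),
      n_faction0 = sum(f == 0), n_faction1 = sum(f == 1),
      contested_gap = gap))
    for (fac in 0:1) {
      hit <- st$stances[f == fac, , drop = FALSE] == tmpl[f == fac, , drop = FALSE]
      consensus <- rbind(consensus, data.frame(
        wave = w$wave_id, item = colnames(tmpl), faction = fac,
        consensus = colMeans(hit, na.rm = TRUE), row.names = NULL))
    }
  }
  list(overview = overview, consensus = consensus)
}

#' Write a cohort to per-wave CSV files plus a ground-truth CSV
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort$waves, function(w) {
    p <- file.path(dir, paste0("wave_", w$wave_id, ".csv"))
    write_wave(w, p)
    p
  }, character(1))
  gt <- file.path(dir, "ground_truth.csv")
  utils::write.csv(
    data.frame(participant_id = names(cohort$truth$faction_of),
               faction = unname(cohort$truth$faction_of)),
    gt, row.names = FALSE)
  invisible(c(paths, gt))
}
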