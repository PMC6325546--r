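# Fixture builders used across the test files. Everything is generated in
# code; no data files.

# deterministic trial set for one participant: response chosen by a rule
# function(asynchrony) -> "left_first"/"right_first"; zero-asynchrony
# designations alternate left/right so counts stay balanced
make_participant_trials <- function(id = "p1", group = "percussion",
                                    rule = function(x) {
                                      ifelse(x > 0, "left_first",
                                             ifelse(x < 0, "right_first",
                                                    "left_first"))
                                    },
                                    rt = 400, blocks = 1:5) {
  grid <- expand.grid(
    motion_type = toj_design$motion_types,
    initial_directions = toj_design$initial_directions,
    asynchrony_ms = toj_design$asynchronies_ms,
    block = blocks,
    set = 1:4,
    stringsAsFactors = FALSE
  )
  response <- rule(grid$asynchrony_ms)
  zero <- grid$asynchrony_ms == 0
  designated <- ifelse(grid$asynchrony_ms > 0, "left_first",
                ifelse(grid$asynchrony_ms < 0, "right_first",
                       ifelse(seq_len(nrow(grid)) %% 2 == 0,
                              "left_first", "right_first")))
  tibble::tibble(
    participant_id = id,
    group = group,
    motion_type = grid$motion_type,
    initial_directions = grid$initial_directions,
    asynchrony_ms = grid$asynchrony_ms,
    response = response,
    designated_correct = response == designated,
    rt_ms = rep_len(rt, nrow(grid)),
    block = as.integer(grid$block)
  )
}

# a participant who responds correctly with a fixed probability on nonzero
# trials (seeded); used for inclusion-screen fixtures
make_probabilistic_participant <- function(id, group, p_correct, seed) {
  withr::with_seed(seed, {
    tr <- make_participant_trials(id, group)
    nz <- tr$asynchrony_ms != 0
    correct_resp <- ifelse(tr$asynchrony_ms > 0, "left_first", "right_first")
    wrong_resp <- ifelse(tr$asynchrony_ms > 0, "right_first", "left_first")
    go_correct <- runif(nrow(tr)) < p_correct
    tr$response[nz] <- ifelse(go_correct[nz], correct_resp[nz], wrong_resp[nz])
    tr$designated_correct[nz] <- go_correct[nz]
    tr
  })
}

# small simulated cohort shared by several files (cheap: 3-4 per group)
small_cohort_trials <- function(seed_cohort = 101L, seed_trials = 102L,
                                n = c(percussion = 3L, brass = 4L,
                                      color_guard = 3L), ...) {
  spec <- cohort_spec(n = n, seed = seed_cohort, ...)
  simulate_trials(sample_cohort(spec), seed = seed_trials)
}

# long-format 4-cell d' values from a plain matrix (participants x cells),
# for the interaction statistics
cells_from_matrix <- function(m) {
  # column order: radial_same, radial_opposite, rotational_same,
  # rotational_opposite
  labels <- data.frame(
    motion_type = c("radial", "radial", "rotational", "rotational"),
    initial_directions = c("same", "opposite", "same", "opposite")
  )
  do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    data.frame(
      participant_id = sprintf("p%02d", i),
      motion_type = labels$motion_type,
      initial_directions = labels$initial_directions,
      dprime = m[i, ]
    )
  })) |> tibble::as_tibble()
}

# exhaustive-enumeration oracle for the pairwise permutation p-value
exact_pairwise_p <- function(d1, d2) {
  pool <- c(d1, d2)
  n1 <- length(d1)
  obs <- median(d1) - median(d2)
  parts <- utils::combn(length(pool), n1)
  stats <- apply(parts, 2, function(idx) {
    median(pool[idx]) - median(pool[-idx])
  })
  mean(stats >= obs)
}

# exhaustive-enumeration oracle for the within-participant interaction
# p-value (all 24^n label assignments; keep n tiny)
exact_interaction_p <- function(m) {
  n <- nrow(m)
  perms <- as.matrix(expand.grid(rep(list(1:24), n)))
  ptab <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  ptab <- ptab[apply(ptab, 1, function(r) length(unique(r)) == 4), ]
  stat <- function(mm) {
    meds <- apply(mm, 2, median)
    (meds[1] - meds[2]) - (meds[3] - meds[4])
  }
  obs <- stat(m)
  stats <- apply(perms, 1, function(pr) {
    mm <- t(vapply(seq_len(n), function(i) m[i, ptab[pr[i], ]], numeric(4)))
    stat(mm)
  })
  mean(stats >= obs)
}
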