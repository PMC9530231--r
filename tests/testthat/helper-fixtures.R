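# Builds a long-format trial table from per-trial specifications.
# Each element of `specs` is a list(study, task, group, initial, revised,
# truth, condition).
make_trials <- function(specs) {
  rows <- lapply(specs, function(s) {
    m <- length(s$initial)
    stopifnot(length(s$revised) == m)
    data.frame(study_id = s$study, task_id = s$task, group_id = s$group,
               subject_id = paste0(s$group, "_s", rep(seq_len(m), 2L)),
               stage = rep(c("initial", "revised"), each = m),
               estimate = c(s$initial, s$revised), truth = s$truth,
               condition = if (is.null(s$condition)) "interactive" else s$condition)
  })
  do.call(rbind, rows)
}

# Small synthetic corpus for fast pipeline tests.
small_config <- function(...) {
  synth_config(n_studies = 2L, tasks_per_study = 6L, groups_per_study = 8L,
               group_size = c(8L, 12L), ...)
}
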