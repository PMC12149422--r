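# Shared small fixtures, built in code and memoized per test file.

small_spec <- function(n = 12, seed = 77)
  cohort_spec(n_patients = n, image_shape = c(20L, 20L, 20L),
              radius_range = c(4, 7), seed = seed)

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(small_spec())
    cache
  }
})

# one small two-habitat volume
small_volume <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(5)
      cache <<- generate_tumor_volume(small_spec(),
                                      data.frame(patient_id = "P001", grade = "high"))
    }
    cache
  }
})
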