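# Shared fixtures, generated once per test run. Small frames keep the
# NN-based tests fast; the scaled-up study conditions live in
# test-acceptance.R.

dice_oracle <- function(a, b) {
  # brute-force pixel counting, independent of dice_coefficient()
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    inter <- inter + a[i] * b[i]
    sa <- sa + a[i]; sb <- sb + b[i]
  }
  if (sa + sb == 0) 1 else 2 * inter / (sa + sb)
}

# one small rendered scene reused across preprocess/labeling tests
fixture_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tree <- grow_vein_tree(subject_spec("fix", "left", 321), c(128, 128))
      cache <<- list(tree = tree,
                     session = render_session(tree, scene_params(), 17))
    }
    cache
  }
})

# small two-session dataset for pairing/matcher tests
fixture_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthesize_dataset(6, 2, seed = 99, dim = c(64, 64))
    cache
  }
})
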