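# Shared desk-scale fixtures for the acceptance suite.  Everything is built
# in code at test time and memoised so the expensive stages (rendering,
# labelling, GAN training) run once per session.

desk_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = desk_cache)) {
    assign(key, force(expr), envir = desk_cache)
  }
  get(key, envir = desk_cache)
}

# 1,000 labelled clean pairs under the imbalanced label law
desk_labeled <- function() {
  memo("labeled", {
    # the imbalanced tail occasionally requests indices above the packing
    # limit; the documented clamping warning is expected here
    ds <- suppressWarnings(render_dataset(1000, seed = 201))
    label_dataset(ds, verbose = FALSE)
  })
}

# histological embedder trained on the desk dataset
desk_embedder <- function() {
  memo("embedder", train_histological_embedder(desk_labeled(), seed = 7))
}

# the desk-scale conditional GAN: 2,000 pairs at 64x64, 50 kimgs, gamma 2
desk_fit <- function() {
  memo("fit", {
    ds <- suppressWarnings(render_dataset(2000, seed = 101))
    lab <- label_dataset(ds, verbose = FALSE)
    train_cgan(lab, cgan_config(total_kimgs = 50, gamma = 2, seed = 1))
  })
}
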