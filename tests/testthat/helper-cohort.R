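# shared heavy fixtures, built once per test run and cached across files;
# problem sizes: icosphere resolution 3 meshes (1280 faces) for cohort-level
# work, reduced particle counts and iteration budgets for optimized models

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, builder(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# peanut cohort at reduced mesh resolution (generator defaults otherwise)
small_peanut_cohort <- function() {
  cached_fixture("cohort_res3", function()
    generate_peanut_cohort(peanut_params(mesh_resolution = 3L)))
}

# the same cohort pushed through shared-boundary extraction
extracted_peanut_cohort <- function() {
  cached_fixture("extracted_res3", function()
    extract_cohort(small_peanut_cohort(), extraction_config()))
}

# a converged reduced-scale shared-boundary model (128/32/32 particles)
converged_shared_model <- function() {
  cached_fixture("model_128", function() {
    cfg <- optimizer_config(mode = "shared_boundary",
                            particles = c(A_r = 128L, M = 32L, B_r = 128L,
                                          C = 32L),
                            iterations = 40L, iterations_per_split = 8L,
                            w = 2, patience = 200L, seed = 7L)
    optimize_particles(extracted_peanut_cohort(), cfg)
  })
}

# tiny two-domain cohort (two spheres side by side), cheap enough for
# optimizer unit tests
tiny_two_domain_cohort <- function(n = 3L, radii = NULL) {
  if (is.null(radii)) radii <- seq(0.9, 1.1, length.out = n)
  lapply(seq_len(n), function(i) {
    multi_organ_sample(
      sprintf("s%02d", i),
      list(left = icosphere(2L, radii[i], c(-1.5, 0, 0)),
           right = icosphere(2L, radii[i], c(1.5, 0, 0))))
  })
}
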