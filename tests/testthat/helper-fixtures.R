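# Shared fixtures: small meshes and a cached standard neuron so the heavier
# pipeline stages run once per session.

cyl_mesh <- function(length_nm = 10000, radius = 500, step = 1000,
                     resolution = 12, caps = TRUE) {
  neurodecomp:::tube_mesh(cbind(0, 0, seq(0, length_nm, step)), radius,
                          resolution, cap_start = caps, cap_end = caps)
}

# T-shaped tube: vertical trunk with one side arm, welded
t_mesh <- function(radius = 500, resolution = 10) {
  p1 <- cbind(0, 0, seq(0, 20000, 1000))
  p2 <- cbind(0, seq(0, 10000, 1000), 10000)
  t1 <- neurodecomp:::tube_mesh(p1, radius, resolution, TRUE, TRUE)
  t2 <- neurodecomp:::tube_mesh(p2, radius, resolution, FALSE, TRUE)
  cat0 <- neurodecomp:::mesh_cat(list(t1, t2), list("trunk", "arm"))
  v <- cat0$mesh$vertices
  ring <- nrow(t1$vertices) + seq_len(resolution)
  collar <- neurodecomp:::weld_collar_faces(v, ring,
                                            seq_len(nrow(t1$vertices)))
  neuro_mesh(v, rbind(cat0$mesh$faces, collar))
}

# one standard spiny neuron taken through the full preprocessing chain,
# cached for the session
std_neuron_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n <- generate_neuron(neuron_params(spine_density = 1), seed = 42)
    mm <- mesh_from_neuron(n, resolution = 10)
    somas <- detect_somas(mm$mesh)
    sk <- skeletonize(mm$mesh, somas)
    co <- mesh_correspondence(mm$mesh, sk)
    g <- decompose(sk, co, somas[[1]], n$synapses)
    cache <<- list(neuron = n, meshed = mm, somas = somas, skeleton = sk,
                   corr = co, graph = g)
    cache
  }
})

# straight-path decomposition graph helper (skeleton-level testing)
path_graph <- function(points, width = 600, compartment = "axon",
                       soma_center = NULL) {
  neurodecomp:::decomp_from_path(points, width = width,
                                 soma_center = soma_center,
                                 compartment = compartment)
}
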