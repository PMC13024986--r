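# small meshes and scenes built in code, shared across test files

unit_square_mesh <- function() {
  triangle_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    faces    = rbind(c(1, 2, 3), c(1, 3, 4))
  )
}

right_triangle_mesh <- function() {
  triangle_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    faces    = rbind(c(1, 2, 3))
  )
}

equilateral_mesh <- function(side = 2) {
  triangle_mesh(
    vertices = rbind(c(0, 0, 0), c(side, 0, 0),
                     c(side / 2, side * sqrt(3) / 2, 0)),
    faces    = rbind(c(1, 2, 3))
  )
}

# a coarse painted cylinder-limb scene: cheap enough for per-test reuse
small_limb_scene <- function(resolution = 2) {
  synthetic_scene("cylinder_limb",
                  anatomy_params = list(radius = 20, length = 80),
                  wound_spec = list(phi_span = pi / 3, patch_length = 25),
                  resolution = resolution)
}

small_painted_limb <- function(resolution = 2) {
  sc <- small_limb_scene(resolution)
  paint_wound(make_anatomy(sc), sc)
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
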