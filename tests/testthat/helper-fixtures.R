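# Fixtures built in code at test time.

# hand-written 2-residue PDB text with known fields
mini_pdb_lines <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 90.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 90.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00 90.00           C",
    "ATOM      4  CA  ALA A   2       3.800   1.400   0.500  1.00 71.25           C",
    "END")
}

# bare model from an atom table sketch (chain A, carbon CA atoms by default)
quick_model <- function(resno, x, y, z, atom_name = "CA", element = "C",
                        residue_name = "ALA", confidence = 90) {
  n <- length(resno)
  structure_model(data.frame(
    serial = seq_len(n),
    atom_name = rep_len(atom_name, n),
    residue_name = rep_len(residue_name, n),
    chain_id = "A",
    residue_number = resno,
    x = x, y = y, z = z,
    element = rep_len(element, n),
    confidence = rep_len(confidence, n),
    stringsAsFactors = FALSE
  ))
}

# straight line of CA atoms exactly on the z axis
line_model <- function(n = 150, spacing = 2) {
  quick_model(seq_len(n), 0, 0, (seq_len(n) - 1) * spacing)
}

# ideal hollow cylinder: rings of carbon atoms at radius `wall_r` around z
cylinder_model <- function(wall_r = 7.7, length = 100, ring_step = 1.5,
                           atoms_per_ring = 16) {
  zs <- seq(0, length, by = ring_step)
  ang <- seq(0, 2 * pi, length.out = atoms_per_ring + 1)[-(atoms_per_ring + 1)]
  g <- expand.grid(z = zs, a = ang)
  quick_model(seq_len(nrow(g)), wall_r * cos(g$a), wall_r * sin(g$a), g$z,
              residue_name = "LEU")
}

# shared default benchmark tube, built once per test run
default_tube <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_tube(seed = 7)
    cache
  }
})

tube_plan_900 <- function() plan_fragments(900, target_len = 400, min_overlap = 100)
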