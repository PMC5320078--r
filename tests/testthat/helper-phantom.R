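# Small, fast phantom configurations used across the unit tests.

smallSpec <- function(...) {
  phantomSpec(gridShape = c(128L, 128L, 9L), ...)
}

cleanSmallSpec <- function(...) {
  smallSpec(noiseSdHu = 0, psfSigmaPx = 0, tiltDeg = 0, shiftPx = c(0, 0), ...)
}

# a tiny CTVolume with a hollow "skull" box enclosing tissue, for I/O and
# skull-stripping contract tests
boxHeadVolume <- function(nx = 40, ny = 40, nz = 4, inside = 40) {
  a <- array(-1000, c(nx, ny, nz))
  a[5:(nx - 4), 5:(ny - 4), ] <- 1000
  a[8:(nx - 7), 8:(ny - 7), ] <- inside
  ctVolume(a, c(0.426, 0.426, 5))
}
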