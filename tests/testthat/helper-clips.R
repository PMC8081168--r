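# Shared fixtures: small media parameters keep rendering fast.

smallMedia <- function(fps = 2, duration = 10, height = 60, width = 80,
                       sampleRate = 8000) {
  list(fps = fps, duration = duration, height = height, width = width,
       sampleRate = sampleRate)
}

defaultMedia <- function() {
  list(fps = 4, duration = 10, height = 90, width = 120,
       sampleRate = 8000)
}

smallConfig <- function(nParticipants = 30, seed = 11, ...) {
  generatorConfig(nParticipants = nParticipants, media = smallMedia(),
                  seed = seed, ...)
}

# a full-scale 1 kHz sine, the calibration reference tone
referenceSine <- function(duration = 2, sampleRate = 8000) {
  tt <- seq_len(duration * sampleRate) / sampleRate
  sin(2 * pi * 1000 * tt)
}
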