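PKG_CXXFLAGS = -fopenmp-simd
# the DP kernel is the package's hot loop; make sure -O3 lands after the
# toolchain's default -O2 in the compile line
CXXFLAGS += -O3
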