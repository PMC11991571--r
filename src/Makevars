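# The toolchain's CXXFLAGS end with -O2, which would cap the optimization of
# these compute kernels; target-specific appends win, restoring -O3. SSE4.2
# (2008-era baseline) lets the vectorizer use libmvec's SIMD exp in the
# -ffast-math activation kernels.
%.o: CXXFLAGS += -O3 -funroll-loops -msse4.2
fastmath.o: PKG_CXXFLAGS += -ffast-math

PKG_LIBS = -lmvec -lm
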